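// Ridge-stabilised IRLS for logistic regression on a standardized design.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export(name = ".irls_cpp")]]
List irls_cpp(const arma::mat& A, const arma::vec& y, double lambda,
              int maxit, double tol) {
  const arma::uword p = A.n_cols;
  arma::vec beta(p, arma::fill::zeros);
  arma::mat pen(p, p, arma::fill::zeros);
  for (arma::uword j = 1; j < p; ++j) pen(j, j) = lambda;  // not the intercept
  bool converged = false;
  for (int it = 0; it < maxit; ++it) {
    arma::vec eta = A * beta;
    arma::vec pr = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = arma::clamp(pr % (1.0 - pr), 1e-10, 1.0);
    arma::vec z = eta + (y - pr) / w;
    arma::mat AtW = A.t();
    AtW.each_row() %= w.t();
    arma::vec beta_new;
    bool ok = arma::solve(beta_new, AtW * A + pen, AtW * z,
                          arma::solve_opts::likely_sympd);
    if (!ok) break;
    double delta = arma::abs(beta_new - beta).max();
    beta = beta_new;
    if (delta < tol) {
      converged = true;
      break;
    }
  }
  return List::create(_["beta"] = beta, _["converged"] = converged);
}
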