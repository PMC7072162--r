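// Maximal information coefficient: equipartition + local-search grid
// optimizer over all shapes (nx, ny) with nx * ny <= n^alpha, both axis
// orderings. The y axis is an equal-frequency partition; the x axis starts
// from equal-frequency cuts refined by hill climbing on mutual information.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// mutual information (bits) of the partition defined by `cuts` (boundary
// positions, 1-based, in the x-sort order) against precomputed cumulative
// y-bin counts C (n+1 x ny, C(r, j) = count of y-bin j among first r points)
static double mi_cuts(const arma::imat& C, const std::vector<int>& cuts,
                      int ny, int n) {
  const int nx = (int)cuts.size() + 1;
  double mi = 0.0;
  std::vector<double> px(nx, 0.0), py(ny, 0.0);
  std::vector<double> cell((size_t)nx * ny, 0.0);
  int lo = 0;
  for (int i = 0; i < nx; ++i) {
    int hi = (i == nx - 1) ? n : cuts[i];
    for (int j = 0; j < ny; ++j) {
      double c = (double)(C(hi, j) - C(lo, j));
      cell[(size_t)i * ny + j] = c;
      px[i] += c;
      py[j] += c;
    }
    lo = hi;
  }
  const double dn = (double)n;
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j) {
      double c = cell[(size_t)i * ny + j];
      if (c > 0.0)
        mi += (c / dn) * std::log2(c * dn / (px[i] * py[j]));
    }
  return mi;
}

// best MI over x-cut positions for one shape, starting from equipartition
static double mi_axis(const arma::imat& C, int nx, int ny, int n) {
  std::vector<int> cuts(nx - 1);
  for (int j = 1; j < nx; ++j) {
    int c = (int)std::lround((double)j * n / nx);
    cuts[j - 1] = std::min(std::max(c, 1), n - 1);
  }
  for (int j = 1; j < nx - 1; ++j)           // keep cuts strictly increasing
    if (cuts[j] <= cuts[j - 1]) cuts[j] = cuts[j - 1] + 1;
  if (cuts.back() > n - 1) return 0.0;

  double best = mi_cuts(C, cuts, ny, n);
  const int offs[8] = {-8, -4, -2, -1, 1, 2, 4, 8};
  for (int pass = 0; pass < 3; ++pass) {
    bool improved = false;
    for (size_t j = 0; j < cuts.size(); ++j) {
      int lo = (j == 0) ? 1 : cuts[j - 1] + 1;
      int hi = (j + 1 == cuts.size()) ? n - 1 : cuts[j + 1] - 1;
      int keep = cuts[j];
      for (int k = 0; k < 8; ++k) {
        int cand = std::min(std::max(keep + offs[k], lo), hi);
        if (cand == cuts[j]) continue;
        int old = cuts[j];
        cuts[j] = cand;
        double v = mi_cuts(C, cuts, ny, n);
        if (v > best + 1e-12) {
          best = v;
          improved = true;
          keep = cand;
        } else {
          cuts[j] = old;
        }
      }
    }
    if (!improved) break;
  }
  return best;
}

// cumulative y-bin counts along the x order
static arma::imat cum_counts(const std::vector<int>& yb, int ny, int n) {
  arma::imat C(n + 1, ny, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < ny; ++j) C(i + 1, j) = C(i, j);
    C(i + 1, yb[i] - 1) += 1;
  }
  return C;
}

// [[Rcpp::export(name = ".mic_cpp")]]
double mic_cpp(IntegerVector posx, IntegerVector posy, double alpha) {
  const int n = posx.size();
  int B = std::max((int)std::floor(std::pow((double)n, alpha)), 4);
  // inverse permutations: position in sort order -> original index
  std::vector<int> ordx(n), ordy(n);
  for (int i = 0; i < n; ++i) {
    ordx[posx[i] - 1] = i;
    ordy[posy[i] - 1] = i;
  }
  double best = 0.0;
  for (int ny = 2; ny <= B / 2; ++ny) {
    std::vector<int> ybA(n), ybB(n);
    for (int i = 0; i < n; ++i) {
      ybA[i] = (int)std::ceil((double)posy[ordx[i]] * ny / n);
      ybB[i] = (int)std::ceil((double)posx[ordy[i]] * ny / n);
    }
    arma::imat CA = cum_counts(ybA, ny, n);
    arma::imat CB = cum_counts(ybB, ny, n);
    for (int nx = 2; nx * ny <= B; ++nx) {
      double nrm = std::log2((double)std::min(nx, ny));
      double v = std::max(mi_axis(CA, nx, ny, n), mi_axis(CB, nx, ny, n));
      best = std::max(best, v / nrm);
    }
  }
  return std::min(best, 1.0);
}
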