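#' @importFrom stats plogis var
NULL

#' Control parameters for imbalance-adjusted bootstrap resampling
#'
#' @param n_samples number of bootstrap samples (paper-scale default 1000;
#'   tests and examples scale this down).
#' @param seed integer seed for the resampling stream (`NULL` = current RNG).
#' @param balance `"class"` (class-balanced draws, the IABR reading used
#'   throughout) or `"stratified"` (plain stratified bootstrap preserving the
#'   observed class ratio).
#' @param threshold probability cutoff for sensitivity/specificity.
#' @param max_retries redraw budget for degenerate out-of-bag sets.
#' @return An object of class `iabr_control`.
#' @export
iabr_control <- function(n_samples = 1000, seed = NULL, balance = "class",
                         threshold = 0.5, max_retries = 100) {
  balance <- match.arg(balance, c("class", "stratified"))
  stopifnot(n_samples >= 1, threshold > 0, threshold < 1, max_retries >= 1)
  structure(list(n_samples = n_samples, seed = seed, balance = balance,
                 threshold = threshold, max_retries = max_retries),
            class = "iabr_control")
}

#' Imbalance-adjusted bootstrap samples
#'
#' Draws `n_samples` training multisets of size `n` with replacement,
#' stratified so the two classes contribute `ceiling(n/2)` (positives) and
#' `floor(n/2)` (negatives) draws from their own instances, balancing the
#' classes regardless of the observed imbalance. The test set of each sample
#' is the out-of-bag set (instances never drawn); samples whose test set is
#' empty or single-class are redrawn.
#'
#' @param labels binary outcome vector (1 = lesion, 0 = healthy tissue).
#' @param cfg `iabr_control`.
#' @return List of `n_samples` lists with integer `train` (multiset) and
#'   `test` (out-of-bag indices).
#' @export
iabr_samples <- function(labels, cfg = iabr_control()) {
  y <- as.numeric(labels)
  stopifnot(all(y %in% c(0, 1)))
  pos <- which(y == 1); neg <- which(y == 0)
  if (length(pos) < 2 || length(neg) < 2)
    stop("each class needs at least 2 instances")
  n <- length(y)
  if (cfg$balance == "class") {
    n_pos <- ceiling(n / 2); n_neg <- n - n_pos
  } else {
    n_pos <- length(pos); n_neg <- length(neg)
  }
  with_seed(cfg$seed, lapply(seq_len(cfg$n_samples), function(b) {
    for (try in seq_len(cfg$max_retries)) {
      train <- c(sample(pos, n_pos, replace = TRUE),
                 sample(neg, n_neg, replace = TRUE))
      test <- setdiff(seq_len(n), train)
      if (length(test) && length(unique(y[test])) == 2)
        return(list(train = train, test = test))
    }
    stop("could not draw a bootstrap sample with a two-class test set")
  }))
}

#' Ridge-stabilized maximum-likelihood logistic regression
#'
#' IRLS fit of a logistic model with a mild L2 penalty (`lambda = 1e-6`) on
#' the standardized-scale slopes, which keeps separable bootstrap samples
#' finite without materially biasing well-conditioned fits. Columns are
#' standardized internally and coefficients are returned on the raw scale;
#' constant columns get coefficient 0.
#'
#' @param X numeric matrix (rows = observations), without intercept column.
#' @param y binary outcome vector.
#' @param lambda ridge weight on standardized slopes.
#' @param maxit,tol IRLS iteration cap and coefficient tolerance.
#' @return List with `coef` (intercept + per-feature raw-scale weights),
#'   `coef_std`, and `converged`.
#' @export
logistic_fit <- function(X, y, lambda = 1e-6, maxit = 50, tol = 1e-10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(X^2) - mu^2)
  sdv[sdv < 1e-12] <- 1                      # constant columns stay at 0
  Z <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  fit <- .irls_cpp(cbind(1, Z), y, lambda, maxit, tol)
  beta <- drop(fit$beta)
  converged <- fit$converged
  slopes <- beta[-1] / sdv
  intercept <- beta[1] - sum(beta[-1] * mu / sdv)
  cf <- c(intercept, slopes)
  names(cf) <- c("(Intercept)", colnames(X))
  list(coef = cf, coef_std = beta, converged = converged)
}

logistic_predict <- function(coef, X) {
  plogis(drop(cbind(1, as.matrix(X)) %*% coef))
}

# rank-based (Mann-Whitney) AUC with mid-rank tie handling
roc_auc <- function(scores, labels) {
  y <- as.numeric(labels)
  n1 <- as.numeric(sum(y == 1)); n0 <- as.numeric(sum(y == 0))
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' The 0.632+ bootstrap estimator
#'
#' Blends the apparent performance with the mean out-of-bag performance using
#' the overfitting-dependent weight of the 0.632+ rule: the relative
#' overfitting `R = (app - oob) / (app - 0.5)` (clipped to `[0, 1]`, and 0
#' whenever `app <= max(oob, 0.5)`) gives `w = 0.632 / (1 - 0.368 R)` and the
#' estimate `(1 - w) * app + w * max(oob, 0.5)`. 0.5 is the no-information
#' value of AUC (and of sensitivity/specificity at a 0.5 cutoff).
#'
#' @param auc_app apparent (resubstitution) performance in `[0, 1]`.
#' @param auc_oob mean out-of-bag performance in `[0, 1]`.
#' @return The 0.632+ estimate.
#' @export
auc_632plus <- function(auc_app, auc_oob) {
  stopifnot(auc_app >= 0, auc_app <= 1, auc_oob >= 0, auc_oob <= 1)
  floor_oob <- max(auc_oob, 0.5)
  R <- if (auc_app <= floor_oob) 0
  else min(max((auc_app - auc_oob) / (auc_app - 0.5), 0), 1)
  w <- 0.632 / (1 - 0.368 * R)
  (1 - w) * auc_app + w * floor_oob
}

# 0.632+ AUC / sensitivity / specificity of one feature combination under a
# fixed set of bootstrap samples
eval_combo <- function(X, y, samples, threshold = 0.5) {
  fit <- logistic_fit(X, y)
  p_app <- logistic_predict(fit$coef, X)
  app <- c(auc = roc_auc(p_app, y),
           sens = mean(p_app[y == 1] >= threshold),
           spec = mean(p_app[y == 0] < threshold))
  oob <- vapply(samples, function(s) {
    f <- logistic_fit(X[s$train, , drop = FALSE], y[s$train])
    p <- logistic_predict(f$coef, X[s$test, , drop = FALSE])
    yt <- y[s$test]
    c(roc_auc(p, yt),
      mean(p[yt == 1] >= threshold),
      mean(p[yt == 0] < threshold))
  }, numeric(3))
  ob <- unname(rowMeans(oob, na.rm = TRUE))
  app <- unname(app)
  list(auc632 = auc_632plus(app[1], ob[1]),
       sens632 = auc_632plus(app[2], ob[2]),
       spec632 = auc_632plus(app[3], ob[3]),
       auc_app = app[1], auc_oob = ob[1])
}

#' Forward model building over orders 1..max_order
#'
#' Builds nested logistic models: the order-1 model is the single reduced
#' feature with the highest 0.632+ bootstrap AUC; each higher order adds the
#' candidate feature that maximizes the 0.632+ AUC of the enlarged model.
#' Every order is scored (AUC, sensitivity, specificity, all 0.632+) on its
#' own fixed bootstrap substream (`cfg$seed + order`), so results do not
#' depend on evaluation order; ties go to the earlier-ranked candidate.
#'
#' @param reduced `mprad_reduced` feature ranking (or character vector of
#'   feature names in rank order).
#' @param table feature table with `label` column.
#' @param cfg `iabr_control`.
#' @param max_order largest model order (default 10).
#' @return An object of class `mprad_models`: per-order results with the
#'   chosen features and 0.632+ performances.
#' @export
forward_build_models <- function(reduced, table, cfg = iabr_control(),
                                 max_order = 10) {
  feats <- if (inherits(reduced, "mprad_reduced")) reduced$feature
  else as.character(reduced)
  stopifnot(length(feats) >= 1)
  if (max_order > length(feats)) {
    warning(sprintf("max_order %d exceeds the %d reduced features; capping",
                    max_order, length(feats)))
    max_order <- length(feats)
  }
  y <- as.numeric(table$label)
  X <- as.matrix(table[, feats, drop = FALSE])

  current <- character(0)
  results <- vector("list", max_order)
  for (i in seq_len(max_order)) {
    cfg_i <- cfg
    if (!is.null(cfg$seed)) cfg_i$seed <- cfg$seed + i
    samples <- iabr_samples(y, cfg_i)
    cand <- setdiff(feats, current)
    evals <- lapply(cand, function(f)
      eval_combo(X[, c(current, f), drop = FALSE], y, samples,
                 cfg$threshold))
    best <- which.max(vapply(evals, `[[`, 0, "auc632"))
    current <- c(current, cand[best])
    fit <- logistic_fit(X[, current, drop = FALSE], y)
    results[[i]] <- c(list(order = i, features = current,
                           coefficients = fit$coef), evals[[best]])
  }
  structure(list(results = results, cfg = cfg, max_order = max_order),
            class = "mprad_models")
}

#' Per-order performance table
#'
#' @param models `mprad_models` from [forward_build_models()].
#' @return Data frame with `order`, `auc632`, `sens632`, `spec632`.
#' @export
performance_table <- function(models) {
  stopifnot(inherits(models, "mprad_models"))
  do.call(rbind, lapply(models$results, function(r)
    data.frame(order = r$order, auc632 = unname(r$auc632),
               sens632 = unname(r$sens632), spec632 = unname(r$spec632))))
}

#' @export
print.mprad_models <- function(x, ...) {
  cat("<mprad_models> forward-built logistic models\n")
  print(performance_table(x), row.names = FALSE)
  invisible(x)
}

#' Choose the best model order
#'
#' The smallest order whose 0.632+ AUC is within `tol` of the maximum (a
#' plateau rule favouring parsimony); `tol = 0` is the literal argmax, with
#' the first maximum winning ties.
#'
#' @param models `mprad_models` (or the data frame from
#'   [performance_table()]).
#' @param tol plateau tolerance on AUC (default 0.005).
#' @return Integer order.
#' @export
choose_best_order <- function(models, tol = 0.005) {
  perf <- if (inherits(models, "mprad_models")) performance_table(models)
  else models
  stopifnot(nrow(perf) >= 1, tol >= 0)
  ok <- perf$auc632 >= max(perf$auc632) - tol
  perf$order[which(ok)[1]]
}

#' Finalize the model for a fixed feature combination
#'
#' Computes the final logistic coefficients for the chosen features under
#' IABR: each bootstrap training multiset is fitted and the raw-scale
#' coefficients are averaged (their bootstrap sd is kept as a stability
#' diagnostic). `method = "refit"` instead fits the full data once.
#'
#' @param features character vector of feature names.
#' @param table feature table with `label`.
#' @param cfg `iabr_control`.
#' @param method `"iabr_mean"` (default) or `"refit"`.
#' @return An object of class `mprad_final`: `features`, `coefficients`,
#'   `coef_sd`, and 0.632+ performances of the combination.
#' @export
finalize_model <- function(features, table, cfg = iabr_control(),
                           method = c("iabr_mean", "refit")) {
  method <- match.arg(method)
  y <- as.numeric(table$label)
  X <- as.matrix(table[, features, drop = FALSE])
  samples <- iabr_samples(y, cfg)
  perf <- eval_combo(X, y, samples, cfg$threshold)
  if (method == "iabr_mean") {
    cfs <- vapply(samples, function(s)
      logistic_fit(X[s$train, , drop = FALSE], y[s$train])$coef,
      numeric(ncol(X) + 1))
    coefficients <- rowMeans(cfs)
    coef_sd <- apply(cfs, 1, sd)
  } else {
    coefficients <- logistic_fit(X, y)$coef
    coef_sd <- rep(NA_real_, length(coefficients))
  }
  structure(list(features = features, coefficients = coefficients,
                 coef_sd = coef_sd, method = method,
                 auc632 = unname(perf$auc632), sens632 = unname(perf$sens632),
                 spec632 = unname(perf$spec632)),
            class = "mprad_final")
}

#' @export
print.mprad_final <- function(x, ...) {
  cat(sprintf("<mprad_final> order-%d logistic model (%s)\n",
              length(x$features), x$method))
  print(round(x$coefficients, 4))
  cat(sprintf("0.632+ AUC %.3f, sensitivity %.3f, specificity %.3f\n",
              x$auc632, x$sens632, x$spec632))
  invisible(x)
}
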