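#' @importFrom stats cor
NULL

#' Spearman rank correlation with mid-ranks
#'
#' Pearson correlation of the mid-ranks (average ranks for ties). A
#' zero-variance input has no rank order and is defined to correlate 0
#' (flagged via the `"degenerate"` attribute).
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    return(structure(0, degenerate = TRUE))
  cor(rx, ry)
}

#' Maximal information coefficient (MIC)
#'
#' Grid-based normalized mutual information: the maximum over grid shapes
#' `(nx, ny)` with `nx * ny <= n^alpha` of `I(grid) / log2(min(nx, ny))`,
#' where each grid starts from equal-frequency partitions and the finer axis
#' is refined by local search; the maximum is also taken over both axis
#' orderings, making the estimate symmetric. Scores 1 for noiseless
#' functional dependence and near 0 for independent variables.
#'
#' @param x,y numeric vectors of equal length (>= 10).
#' @param alpha grid-resolution exponent (default 0.6, the MINE convention).
#' @return MIC estimate in `[0, 1]`.
#' @export
mic <- function(x, y, alpha = 0.6) {
  stopifnot(length(x) == length(y), length(x) >= 10)
  n <- length(x)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(0)
  .mic_cpp(as.integer(rank(x, ties.method = "first")),
           as.integer(rank(y, ties.method = "first")), alpha)
}

#' Stepwise gain-based feature reduction
#'
#' Reduces a feature table to the `k` top-ranked features. The first feature
#' maximizes the absolute Spearman correlation with the outcome; each
#' subsequent feature maximizes
#' `gain(f) = delta * |spearman(f, outcome)| -
#' (1 - delta) * mean(MIC(f, s))` over the already-selected features `s`,
#' penalizing redundancy. The procedure is deterministic: ties break on
#' lexicographic feature name, and constant features are only admitted once
#' the non-constant ones are exhausted.
#'
#' @param table `mprad_features` data frame (or any data frame with a binary
#'   `label` column and numeric feature columns).
#' @param k target number of features (default 25).
#' @param delta weight of the relevance term in `[0, 1]` (default 0.5).
#' @return An object of class `mprad_reduced`: data frame with `rank`,
#'   `feature` and `gain`.
#' @export
reduce_feature_set <- function(table, k = 25, delta = 0.5) {
  stopifnot(k >= 1, delta >= 0, delta <= 1)
  fc <- feature_columns(table)
  y <- table$label
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  X <- as.matrix(table[, fc, drop = FALSE])
  nf <- length(fc)
  if (k > nf) {
    warning(sprintf("k = %d exceeds the %d available features; returning all",
                    k, nf))
    k <- nf
  }
  is_const <- apply(X, 2, function(v) length(unique(v)) < 2)
  rho <- vapply(seq_len(nf), function(j)
    if (is_const[j]) 0 else abs(spearman_corr(X[, j], y)), 0)

  ord <- order(fc)                           # lexicographic tie-break order
  micmat <- matrix(NA_real_, nf, nf)
  selected <- integer(0)
  gains <- numeric(0)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(nf), selected)
    live <- cand[!is_const[cand]]
    if (!length(live)) live <- cand          # only constants remain
    gain <- vapply(live, function(j) {
      if (!length(selected)) return(delta * rho[j])
      pen <- vapply(selected, function(s) {
        if (is.na(micmat[j, s])) {
          v <- if (is_const[j] || is_const[s]) 0 else mic(X[, j], X[, s])
          micmat[j, s] <<- micmat[s, j] <<- v
        }
        micmat[j, s]
      }, 0)
      delta * rho[j] - (1 - delta) * mean(pen)
    }, 0)
    # argmax with lexicographic-name tie-break
    top <- live[gain >= max(gain) - 1e-15]
    pick <- top[which.min(match(top, ord))]
    selected <- c(selected, pick)
    gains <- c(gains, gain[match(pick, live)])
  }
  structure(data.frame(rank = seq_along(selected), feature = fc[selected],
                       gain = gains, stringsAsFactors = FALSE),
            delta = delta, class = c("mprad_reduced", "data.frame"))
}
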