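#' Fit the full radiomic classification model
#'
#' The package's top-level fitting function: from a segmentations-by-features
#' table with a binary `label` outcome (lesion = 1, healthy tissue = 0) it
#' (1) reduces the features to the `k` top-ranked by the Spearman + MIC gain,
#' (2) forward-builds logistic models of order `1..max_order` maximizing the
#' 0.632+ bootstrap AUC under imbalance-adjusted bootstrap resampling,
#' (3) picks the best order (plateau rule on AUC) and (4) finalizes the
#' coefficients for that combination under IABR.
#'
#' @param table feature table, e.g. from [extract_feature_table()].
#' @param k reduced-set size (default 25).
#' @param delta relevance weight of the reduction gain (default 0.5).
#' @param max_order largest model order (default 10).
#' @param control `iabr_control` bootstrap settings.
#' @param tol plateau tolerance for the best-order choice.
#' @return An object of class `radiomic_model` with components `reduced`
#'   (feature ranking), `models` (per-order results), `best_order`, `final`
#'   (finalized coefficients and performances).
#' @seealso [predict.radiomic_model()], [plot.radiomic_model()]
#' @examples
#' set.seed(1)
#' toy <- data.frame(label = rep(c(1, 0), each = 15),
#'                   f1 = rnorm(30, rep(c(1, -1), each = 15)),
#'                   f2 = rnorm(30))
#' m <- radiomic_model(toy, k = 2, max_order = 2,
#'                     control = iabr_control(n_samples = 20, seed = 1))
#' coef(m)
#' @export
radiomic_model <- function(table, k = 25, delta = 0.5, max_order = 10,
                           control = iabr_control(), tol = 0.005) {
  cl <- match.call()
  reduced <- reduce_feature_set(table, k = k, delta = delta)
  models <- forward_build_models(reduced, table, control,
                                 max_order = max_order)
  best <- choose_best_order(models, tol = tol)
  final <- finalize_model(models$results[[best]]$features, table, control)
  structure(list(call = cl, task = attr(table, "model"),
                 reduced = reduced, models = models, best_order = best,
                 final = final, control = control,
                 n = nrow(table), n_pos = sum(table$label == 1)),
            class = "radiomic_model")
}

#' @export
print.radiomic_model <- function(x, ...) {
  cat("Radiomic logistic classifier",
      if (!is.null(x$task)) sprintf("(task %s)", x$task), "\n")
  cat(sprintf("  %d segmentations (%d lesion / %d healthy), %d reduced features\n",
              x$n, x$n_pos, x$n - x$n_pos, nrow(x$reduced)))
  cat(sprintf("  best order %d: 0.632+ AUC %.3f (sens %.3f, spec %.3f)\n",
              x$best_order, x$final$auc632, x$final$sens632, x$final$spec632))
  cat("  features:", paste(x$final$features, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.radiomic_model <- function(object, ...) {
  out <- list(task = object$task, perf = performance_table(object$models),
              best_order = object$best_order, final = object$final,
              reduced = object$reduced)
  class(out) <- "summary.radiomic_model"
  out
}

#' @export
print.summary.radiomic_model <- function(x, ...) {
  cat("Per-order 0.632+ performance:\n")
  print(x$perf, row.names = FALSE)
  cat(sprintf("\nBest order: %d\nFinal coefficients (IABR mean):\n",
              x$best_order))
  print(round(x$final$coefficients, 4))
  invisible(x)
}

#' @export
coef.radiomic_model <- function(object, ...) object$final$coefficients

#' Predict lesion probability from a fitted radiomic model
#'
#' @param object `radiomic_model`.
#' @param newdata data frame containing the final model's feature columns.
#' @param type `"response"` (probability), `"link"` (logit) or `"class"`
#'   (0/1 at the control threshold).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.radiomic_model <- function(object, newdata,
                                   type = c("response", "link", "class"),
                                   ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata[, object$final$features, drop = FALSE])
  eta <- drop(cbind(1, X) %*% object$final$coefficients)
  switch(type,
         link = eta,
         response = plogis(eta),
         class = as.numeric(plogis(eta) >= object$control$threshold))
}

#' Plot per-order 0.632+ performance
#'
#' AUC (solid), sensitivity (dashed) and specificity (dotted) versus model
#' order, the package's analogue of the order-performance curves used to
#' compare classification tasks.
#'
#' @param x `radiomic_model`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.radiomic_model <- function(x, ...) {
  perf <- performance_table(x$models)
  graphics::matplot(perf$order, perf[, c("auc632", "sens632", "spec632")],
                    type = "l", lty = 1:3, col = c("black", "red", "blue"),
                    xlab = "model order", ylab = "0.632+ estimate",
                    ylim = c(0, 1), ...)
  graphics::abline(v = x$best_order, col = "grey", lty = 4)
  graphics::legend("bottomright", c("AUC", "sensitivity", "specificity"),
                   lty = 1:3, col = c("black", "red", "blue"), bty = "n")
  invisible(x)
}
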