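#' @importFrom stats dist
NULL

first_order_names <- c("energy", "entropy", "kurtosis", "max", "mean", "mad",
                       "median", "min", "rms", "skewness", "std",
                       "uniformity", "variance")

glcm_feature_names <- c("energy", "contrast", "entropy", "homogeneity",
                        "correlation", "sum_average", "variance",
                        "dissimilarity", "autocorrelation")

all_map_names <- c("T2W", "ADC", "D", "K", "Ktrans", "Kep", "ve", "iAUC")

#' First-order radiomic features of a normalized region
#'
#' The 13 histogram/moment statistics of the clamped in-mask intensity
#' distribution: energy, entropy, kurtosis, maximum, mean, mean absolute
#' deviation, median, minimum, root mean square, skewness, standard
#' deviation, uniformity and variance. Entropy and uniformity are computed on
#' the probability histogram over `nbins` equal-width bins spanning the
#' clamped range; moments are population moments of the raw clamped values;
#' kurtosis is non-excess (a normal distribution scores 3). A constant region
#' is degenerate: skewness and kurtosis are defined as 0, entropy 0,
#' uniformity 1.
#'
#' @param region `mprad_region` from [normalize_intensities()].
#' @param nbins histogram bins (default 256).
#' @return Named numeric vector of length 13.
#' @export
first_order_features <- function(region, nbins = 256) {
  stopifnot(inherits(region, "mprad_region"))
  x <- region$values
  n <- length(x)
  mu <- mean(x)
  m2 <- sum((x - mu)^2) / n
  if (region$sigma > 0 && region$hi > region$lo) {
    p <- tabulate(quantize_values(x, region$lo, region$hi, nbins), nbins) / n
    p <- p[p > 0]
    entropy <- -sum(p * log2(p))
    uniformity <- sum(p^2)
  } else {
    entropy <- 0
    uniformity <- 1
  }
  skew <- if (m2 > 0) (sum((x - mu)^3) / n) / m2^1.5 else 0
  kurt <- if (m2 > 0) (sum((x - mu)^4) / n) / m2^2 else 0
  c(energy = sum(x^2), entropy = entropy, kurtosis = kurt,
    max = max(x), mean = mu, mad = sum(abs(x - mu)) / n,
    median = median(x), min = min(x), rms = sqrt(sum(x^2) / n),
    skewness = skew, std = sqrt(m2), uniformity = uniformity,
    variance = m2)
}

# the 13 unique displacement directions of the 26-neighbourhood (distance 1),
# taking the lexicographically positive half of each +/- pair
offsets_3d <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  keep <- g$dx > 0 | (g$dx == 0 & g$dy > 0) |
    (g$dx == 0 & g$dy == 0 & g$dz > 0)
  as.matrix(g[keep, ])
}

# the 4 unique in-plane directions of 8-connectivity
offsets_2d <- function() {
  cbind(dx = c(1, 0, 1, 1), dy = c(0, 1, 1, -1), dz = c(0, 0, 0, 0))
}

#' Gray-level co-occurrence matrix of a quantized region
#'
#' Accumulates level pairs over the 13 unique directions of the 3D
#' 26-neighbourhood at distance 1 (all 3D directions merged into a single
#' matrix), with both voxels inside the mask, symmetrizes and normalizes to
#' sum 1. Regions living on a single axial slice use the 4 unique in-plane
#' directions of 8-connectivity instead. A single-voxel mask has no pairs and
#' yields a degenerate all-zero matrix (flagged via the `"degenerate"`
#' attribute).
#'
#' @param qvol integer array of grey levels in `1..levels` (`NA` outside the
#'   mask), e.g. `quantize_region()$qvol`.
#' @param mask logical array, same shape.
#' @param levels number of grey levels (default 32).
#' @return `levels x levels` matrix summing to 1 (or 0 if degenerate).
#' @export
build_glcm <- function(qvol, mask, levels = 32) {
  stopifnot(identical(dim(qvol), dim(mask)), levels >= 2)
  dims <- dim(qvol)
  slices <- unique(which(mask, arr.ind = TRUE)[, 3])
  offs <- if (length(slices) <= 1) offsets_2d() else offsets_3d()
  L <- as.integer(levels)
  counts <- numeric(L * L)
  q <- qvol
  q[!mask] <- NA_integer_
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    sx <- seq(max(1, 1 - o[1]), min(dims[1], dims[1] - o[1]))
    sy <- seq(max(1, 1 - o[2]), min(dims[2], dims[2] - o[2]))
    sz <- seq(max(1, 1 - o[3]), min(dims[3], dims[3] - o[3]))
    if (!length(sx) || !length(sy) || !length(sz)) next
    a <- q[sx, sy, sz, drop = FALSE]
    b <- q[sx + o[1], sy + o[2], sz + o[3], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    counts <- counts + tabulate((a[ok] - 1L) * L + b[ok], L * L)
  }
  C <- matrix(counts, L, L)
  C <- C + t(C)                              # symmetrize (i,j) and (j,i)
  tot <- sum(C)
  if (tot == 0)
    return(structure(matrix(0, L, L), degenerate = TRUE))
  C / tot
}

#' Haralick features of a normalized GLCM
#'
#' Nine second-order texture statistics of a co-occurrence matrix `P`
#' (summing to 1): energy, contrast, entropy, homogeneity, correlation, sum
#' average, variance, dissimilarity and autocorrelation. Variance uses
#' deviations from the marginal mean; sum average is the classic Haralick sum
#' over `k = 2..2L` of the diagonal-sum distribution. A zero-variance
#' marginal defines correlation as 0; a degenerate (pair-free) matrix scores
#' 0 everywhere except energy and homogeneity, defined as 1.
#'
#' @param P normalized GLCM, e.g. from [build_glcm()].
#' @return Named numeric vector of length 9.
#' @export
glcm_features <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  L <- nrow(P)
  if (isTRUE(attr(P, "degenerate")) || sum(P) == 0) {
    out <- setNames(numeric(9), glcm_feature_names)
    out["energy"] <- 1; out["homogeneity"] <- 1
    return(out)
  }
  if (abs(sum(P) - 1) > 1e-8) stop("GLCM must sum to 1")
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mui <- sum(seq_len(L) * px); muj <- sum(seq_len(L) * py)
  s2i <- sum((seq_len(L) - mui)^2 * px); s2j <- sum((seq_len(L) - muj)^2 * py)
  pos <- P > 0
  pxy <- vapply(2:(2 * L), function(k) sum(P[i + j == k]), 0)
  c(energy = sum(P^2),
    contrast = sum((i - j)^2 * P),
    entropy = -sum(P[pos] * log2(P[pos])),
    homogeneity = sum(P / (1 + abs(i - j))),
    correlation = if (s2i > 0 && s2j > 0)
      sum((i - mui) * (j - muj) * P) / sqrt(s2i * s2j) else 0,
    sum_average = sum((2:(2 * L)) * pxy),
    variance = sum((i - mui)^2 * P),
    dissimilarity = sum(abs(i - j) * P),
    autocorrelation = sum(i * j * P))
}

model_map_catalog <- function(model) {
  switch(model,
         std3D = c("T2W", "ADC"),
         adv3D = all_map_names,
         adv2D = all_map_names)
}

#' Extract the feature table for one classification task
#'
#' Builds the segmentations-by-features table feeding the classifiers:
#' * `std3D` - 13 first-order + 9 GLCM features from each of T2W and ADC on
#'   the 3D VOI (44 columns);
#' * `adv3D` - 13 first-order features from each of the 8 maps on the 3D VOI
#'   (104 columns);
#' * `adv2D` - as `adv3D` but on the derived 2D ROI (slice with the longest
#'   major axis), with normalization recomputed on the slice.
#'
#' Columns are named `map.order.statistic` (e.g. `ADC.first.mean`,
#' `T2W.second.contrast`); the outcome column `label` codes lesion = 1,
#' healthy tissue = 0.
#'
#' @param cohort `mprad_cohort` with maps attached
#'   (see [compute_cohort_maps()]).
#' @param model one of `"std3D"`, `"adv3D"`, `"adv2D"`.
#' @param nbins first-order histogram bins.
#' @param glcm_levels grey levels for the co-occurrence matrix.
#' @return A data frame (class `mprad_features`) with `voi_id`,
#'   `subject_id`, `label` and one column per feature.
#' @export
extract_feature_table <- function(cohort, model = c("std3D", "adv3D", "adv2D"),
                                  nbins = 256, glcm_levels = 32) {
  stopifnot(inherits(cohort, "mprad_cohort"))
  model <- match.arg(model)
  needed <- model_map_catalog(model)
  studies <- setNames(cohort$studies,
                      vapply(cohort$studies, `[[`, 0, "subject_id"))

  rows <- lapply(cohort$segmentations, function(seg) {
    st <- studies[[as.character(seg$subject_id)]]
    missing <- setdiff(needed, names(st$maps))
    if (length(missing))
      stop(sprintf("model %s requires missing map(s): %s (run compute_cohort_maps)",
                   model, paste(missing, collapse = ", ")))
    use_seg <- if (model == "adv2D") extract_2d_roi(seg) else seg
    feats <- unlist(lapply(needed, function(mn) {
      region <- normalize_intensities(st$maps[[mn]], use_seg)
      fo <- first_order_features(region, nbins)
      names(fo) <- paste(mn, "first", names(fo), sep = ".")
      if (model == "std3D") {
        qr <- quantize_region(region, glcm_levels)
        so <- glcm_features(build_glcm(qr$qvol, use_seg$mask$data, glcm_levels))
        names(so) <- paste(mn, "second", names(so), sep = ".")
        c(fo, so)
      } else fo
    }))
    c(voi_id = seg$voi_id, subject_id = seg$subject_id,
      label = as.numeric(seg$label == "lesion"), feats)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  if (!all(is.finite(as.matrix(tab))))
    stop("non-finite feature values in the table")
  structure(tab, model = model,
            feature_cols = setdiff(names(tab),
                                   c("voi_id", "subject_id", "label")),
            class = c("mprad_features", "data.frame"))
}

#' Feature column names of a feature table
#' @param table `mprad_features` data frame.
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(table) {
  fc <- attr(table, "feature_cols")
  if (is.null(fc)) setdiff(names(table), c("voi_id", "subject_id", "label"))
  else fc
}
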