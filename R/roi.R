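#' @importFrom stats approx
#' @importFrom utils head
#' @importFrom grDevices chull
NULL

# longest pairwise distance between in-mask pixel centres of one axial slice,
# in physical units (Feret diameter); convex hull first to keep it O(h^2)
slice_major_axis <- function(slice_mask, spacing) {
  idx <- which(slice_mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(-Inf)
  if (nrow(idx) == 1) return(0)
  pts <- cbind(idx[, 1] * spacing[1], idx[, 2] * spacing[2])
  if (nrow(pts) > 3) pts <- pts[chull(pts), , drop = FALSE]
  max(dist(pts))
}

#' Derive the 2D ROI from a 3D VOI
#'
#' Picks the axial slice whose in-plane mask has the longest major axis,
#' measured as the maximum pairwise Euclidean distance between in-mask pixel
#' centres in physical units. Ties go to the smallest slice index, making the
#' rule deterministic.
#'
#' @param voi 3D `segmentation_record`.
#' @return A 2D `segmentation_record` on the winning slice.
#' @export
extract_2d_roi <- function(voi) {
  stopifnot(inherits(voi, "segmentation_record"))
  if (voi$roi_dim != "3D") stop("`voi` must be a 3D segmentation")
  m <- voi$mask$data
  lens <- vapply(seq_len(dim(m)[3]), function(k)
    slice_major_axis(m[, , k], voi$mask$spacing), 0)
  best <- which.max(lens)                    # first maximum = smallest index
  m2 <- array(FALSE, dim(m))
  m2[, , best] <- m[, , best]
  segmentation_record(voi$subject_id, voi$label,
                      volume(m2, voi$mask$spacing, voi$mask$origin),
                      roi_dim = "2D", slice_index = best, voi_id = voi$voi_id)
}

#' Normalize intensities within a segmentation
#'
#' Computes the in-mask mean and population standard deviation and clamps the
#' in-mask intensities to `[mu - 3 sigma, mu + 3 sigma]`, the dynamics
#' limiting applied before histogram and texture analysis. A constant region
#' is returned unchanged with `lo = hi = mu`.
#'
#' @param vol `mprad_volume` of intensities (e.g. a parameter map).
#' @param seg `segmentation_record` on the same grid.
#' @return An object of class `mprad_region`: clamped `values`, `mu`,
#'   `sigma`, clamp bounds `lo`/`hi`, plus the mask geometry needed by
#'   texture analysis.
#' @export
normalize_intensities <- function(vol, seg) {
  stopifnot(is_volume(vol), inherits(seg, "segmentation_record"))
  if (!identical(dim(vol$data), dim(seg$mask$data)))
    stop("volume and mask grids differ")
  x <- vol$data[seg$mask$data]
  if (any(!is.finite(x))) stop("non-finite intensities inside the mask")
  n <- length(x)
  mu <- mean(x)
  sigma <- sqrt(sum((x - mu)^2) / n)         # population sd
  lo <- mu - 3 * sigma; hi <- mu + 3 * sigma
  structure(list(values = pmin(pmax(x, lo), hi), mu = mu, sigma = sigma,
                 lo = lo, hi = hi, mask = seg$mask, roi_dim = seg$roi_dim),
            class = "mprad_region")
}

#' Quantize a normalized region onto equal-width grey levels
#'
#' Uniform-width bins over the clamped range `[lo, hi]` of the region; the
#' value `hi` maps to the top level, and a constant region (`lo == hi`) maps
#' entirely to level 1.
#'
#' @param region `mprad_region` from [normalize_intensities()].
#' @param levels number of grey levels (>= 2).
#' @return List with `qvol` (integer array, `NA` outside the mask), `qvals`
#'   (integer vector of in-mask levels) and `levels`.
#' @export
quantize_region <- function(region, levels) {
  stopifnot(inherits(region, "mprad_region"), levels >= 2)
  q <- quantize_values(region$values, region$lo, region$hi, levels)
  a <- array(NA_integer_, dim(region$mask$data))
  a[region$mask$data] <- q
  list(qvol = a, qvals = q, levels = as.integer(levels))
}

quantize_values <- function(x, lo, hi, levels) {
  if (hi <= lo) return(rep(1L, length(x)))
  pmin(as.integer(floor((x - lo) / (hi - lo) * levels)) + 1L, as.integer(levels))
}
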