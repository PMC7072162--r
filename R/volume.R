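#' 3D scalar volume on a regular grid
#'
#' The common currency of all maps and masks in the package: a 3D array with a
#' physical voxel spacing and origin. Voxel centre `(i, j, k)` sits at physical
#' position `origin + (c(i, j, k) - 1) * spacing` (millimetres).
#'
#' @param data numeric or logical 3D array.
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @param origin numeric length-3, physical position of the first voxel centre.
#' @return An object of class `mprad_volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!(is.array(data) && length(dim(data)) == 3L))
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "mprad_volume")
}

is_volume <- function(x) inherits(x, "mprad_volume")

#' @export
dim.mprad_volume <- function(x) dim(x$data)

#' @export
print.mprad_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mprad_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x ")))
  v <- x$data[is.finite(x$data)]
  if (length(v))
    cat(sprintf("  range [%g, %g]\n", min(v), max(v)))
  invisible(x)
}

# physical coordinates of voxel centres along one axis
axis_coords <- function(vol, axis) {
  n <- dim(vol$data)[axis]
  vol$origin[axis] + (seq_len(n) - 1) * vol$spacing[axis]
}

# half-voxel-padded physical extent along each axis
vol_extent <- function(vol) {
  d <- dim(vol$data)
  lo <- vol$origin - vol$spacing / 2
  hi <- vol$origin + (d - 1) * vol$spacing + vol$spacing / 2
  cbind(lo = lo, hi = hi)
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Resample a volume onto a reference grid
#'
#' Trilinear interpolation in physical coordinates, as used to bring diffusion
#' and pharmacokinetic maps onto the T2W grid before feature extraction.
#' Target positions outside the source extent take the nearest-edge value.
#' When the two grids are identical the input is returned unchanged.
#'
#' @param vol `mprad_volume` to resample.
#' @param ref `mprad_volume` (or list with `spacing`, `origin` and a `dim`
#'   attribute through a volume) defining the target grid.
#' @return `mprad_volume` on the grid of `ref`.
#' @export
resample_to_reference <- function(vol, ref) {
  stopifnot(is_volume(vol), is_volume(ref))
  if (same_grid(vol, ref)) return(vol)
  es <- vol_extent(vol); er <- vol_extent(ref)
  if (any(er[, "lo"] > es[, "hi"]) || any(er[, "hi"] < es[, "lo"]))
    stop("source and reference grids have disjoint physical extents")

  dsrc <- dim(vol$data)
  # per-axis fractional source indices of the target voxel centres, clamped so
  # that out-of-extent targets replicate the nearest edge value
  idx <- lapply(1:3, function(ax) {
    fi <- (axis_coords(ref, ax) - vol$origin[ax]) / vol$spacing[ax] + 1
    pmin(pmax(fi, 1), dsrc[ax])
  })
  lo <- lapply(1:3, function(ax) pmin(floor(idx[[ax]]), dsrc[ax] - (dsrc[ax] > 1)))
  wt <- lapply(1:3, function(ax) idx[[ax]] - lo[[ax]])

  dref <- dim(ref$data)
  ii <- rep(seq_len(dref[1]), times = dref[2] * dref[3])
  jj <- rep(rep(seq_len(dref[2]), each = dref[1]), times = dref[3])
  kk <- rep(seq_len(dref[3]), each = dref[1] * dref[2])

  out <- numeric(prod(dref))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    xi <- pmin(lo[[1]][ii] + dx, dsrc[1])
    yi <- pmin(lo[[2]][jj] + dy, dsrc[2])
    zi <- pmin(lo[[3]][kk] + dz, dsrc[3])
    w <- (if (dx) wt[[1]][ii] else 1 - wt[[1]][ii]) *
         (if (dy) wt[[2]][jj] else 1 - wt[[2]][jj]) *
         (if (dz) wt[[3]][kk] else 1 - wt[[3]][kk])
    out <- out + w * vol$data[cbind(xi, yi, zi)]
  }
  volume(array(out, dref), spacing = ref$spacing, origin = ref$origin)
}
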