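#' @importFrom stats optim lm.fit coef
NULL

#' Monoexponential ADC fit
#'
#' Log-linear least-squares slope of `-log(S)` versus b, restricted to
#' b-values up to `bmax` (clinical in-line convention: 0-1500 s/mm^2).
#' Non-positive signals are excluded; with fewer than two usable points the
#' fit is degenerate and returns 0.
#'
#' @param signal per-b signal vector.
#' @param bvals b-values (s/mm^2), same length.
#' @param bmax highest b-value used (default 1500).
#' @return `adc_hat` in mm^2/s with a `"status"` attribute
#'   (`"converged"` or `"degenerate"`).
#' @export
fit_adc <- function(signal, bvals, bmax = 1500) {
  stopifnot(length(signal) == length(bvals))
  keep <- bvals <= bmax & is.finite(signal) & signal > 0
  b <- bvals[keep]; y <- log(signal[keep])
  if (length(b) < 2 || length(unique(b)) < 2)
    return(structure(0, status = "degenerate"))
  slope <- sum((b - mean(b)) * (y - mean(y))) / sum((b - mean(b))^2)
  structure(max(-slope, 0), status = "converged")
}

# residual machinery of the DKI model on the signal scale
dki_rss <- function(par, b, y) {
  f <- dki_signal(par[1], par[2], par[3], b)
  sum((f - y)^2)
}

dki_grad <- function(par, b, y) {
  f <- dki_signal(par[1], par[2], par[3], b)
  r <- f - y
  c(2 * sum(r * f) / par[1],
    2 * sum(r * f * (-b + b^2 * par[2] * par[3] / 3)),
    2 * sum(r * f * b^2 * par[2]^2 / 6))
}

#' Diffusion-kurtosis (DKI) fit for one voxel
#'
#' Fits `S(b) = S0 exp(-b D + b^2 D^2 K / 6)` by constrained nonlinear least
#' squares (`D` in `[0, 4e-3]` mm^2/s, `K` in `[0, 3]`), started from the
#' log-quadratic solution, which is exact on noiseless data. The monoexponential
#' ADC of the same voxel is carried along for nested-model checks.
#'
#' @param signal per-b signal vector (>= 3 distinct b-values).
#' @param bvals b-values (s/mm^2).
#' @param bmax_adc b cutoff passed to [fit_adc()] for the companion ADC.
#' @return An object of class `dki_fit`: `s0_hat`, `d_hat`, `k_hat`,
#'   `adc_hat`, `rss`, `status` (`converged`, `clamped` or `degenerate`).
#' @export
fit_dki <- function(signal, bvals, bmax_adc = 1500) {
  stopifnot(length(signal) == length(bvals))
  adc <- fit_adc(signal, bvals, bmax_adc)
  keep <- is.finite(signal) & signal > 0
  b <- bvals[keep]; y <- signal[keep]
  out <- function(s0, d, k, rss, status)
    structure(list(s0_hat = unname(s0), d_hat = unname(d), k_hat = unname(k),
                   adc_hat = as.numeric(adc), rss = unname(rss),
                   status = status),
              class = "dki_fit")
  if (length(unique(b)) < 3)
    return(out(if (length(y)) max(y) else 0, 0, 0, 0, "degenerate"))
  ly <- log(y)
  if (max(ly) - min(ly) < 1e-12)             # constant signal: no decay
    return(out(mean(y), 0, 0, 0, "degenerate"))

  # log-quadratic start: log S = c0 - c1 b + c2 b^2/6, c1 = D, c2 = D^2 K
  co <- lm.fit(cbind(1, -b, b^2 / 6), ly)$coefficients
  d0 <- min(max(co[2], 1e-6), 4e-3)
  k0 <- min(max(co[3] / d0^2, 0), 3)
  p0 <- c(exp(co[1]), d0, k0)

  fit <- optim(p0, dki_rss, dki_grad, b = b, y = y,
               method = "L-BFGS-B",
               lower = c(1e-8, 0, 0), upper = c(Inf, 4e-3, 3),
               control = list(factr = 10, pgtol = 0, maxit = 200,
                              parscale = c(max(p0[1], 1), 1e-3, 1)))
  status <- if (fit$convergence != 0) "not_converged"
  else if (fit$par[2] >= 4e-3 - 1e-9 || fit$par[3] >= 3 - 1e-9) "clamped"
  else "converged"
  out(fit$par[1], fit$par[2], fit$par[3], fit$value, status)
}

#' @export
print.dki_fit <- function(x, ...) {
  cat(sprintf("<dki_fit> S0 = %.4g, D = %.4g mm^2/s, K = %.4g (%s)\n",
              x$s0_hat, x$d_hat, x$k_hat, x$status))
  invisible(x)
}

# profile RSS over kep: ktrans is linear given kep, so solve it in closed form
tofts_profile <- function(kep, times, cp, y, yy) {
  g <- tofts_conv(1, kep, times, cp)
  gg <- sum(g * g)
  if (gg <= 0) return(list(rss = yy, ktrans = 0))
  kt <- max(sum(y * g) / gg, 0)
  list(rss = yy - 2 * kt * sum(y * g) + kt^2 * gg, ktrans = kt)
}

#' Standard Tofts model fit for one tissue curve
#'
#' Nonlinear least squares over `(Ktrans, kep)` against the convolution of the
#' population AIF with an exponential kernel; `Ktrans` is profiled out (it
#' enters linearly), leaving a 1D search over `kep` (coarse log grid followed
#' by local refinement). `ve` is derived as `Ktrans / kep`; `iAUC` is computed
#' from the observed curve by [compute_iauc()].
#'
#' @param curve tissue concentration curve (mM), >= 5 time points.
#' @param times acquisition times (min).
#' @param aif `aif_params`.
#' @param kep_range search interval for `kep` (1/min).
#' @return An object of class `pk_fit`: `ktrans_hat`, `kep_hat`, `ve_hat`,
#'   `iauc_hat`, `rss`, `status`.
#' @export
fit_tofts <- function(curve, times, aif = aif_params(),
                      kep_range = c(1e-3, 10)) {
  stopifnot(length(curve) == length(times), length(times) >= 5)
  cp <- population_aif(times, aif)
  iauc <- compute_iauc(curve, times)
  yy <- sum(curve^2)
  out <- function(kt, kep, rss, status)
    structure(list(ktrans_hat = unname(kt), kep_hat = unname(kep),
                   ve_hat = if (kep > 0) kt / kep else 0,
                   iauc_hat = as.numeric(iauc), rss = rss, status = status),
              class = "pk_fit")
  if (max(abs(curve)) < 1e-12 || max(cp) <= 0)
    return(out(0, kep_range[1], yy, "degenerate"))

  lk <- log(kep_range)
  grid <- exp(seq(lk[1], lk[2], length.out = 40))
  rss <- vapply(grid, function(k) tofts_profile(k, times, cp, curve, yy)$rss,
                0)
  j <- which.min(rss)
  lo <- if (j == 1) lk[1] else log(grid[j - 1])
  hi <- if (j == length(grid)) lk[2] else log(grid[j + 1])
  opt <- optimize(function(l) tofts_profile(exp(l), times, cp, curve, yy)$rss,
                  c(lo, hi), tol = 1e-10)
  kep <- exp(opt$minimum)
  pr <- tofts_profile(kep, times, cp, curve, yy)
  status <- if (pr$ktrans == 0) "degenerate"
  else if (kep <= kep_range[1] * 1.01 || kep >= kep_range[2] * 0.99) "clamped"
  else "converged"
  out(pr$ktrans, kep, pr$rss, status)
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf(
    "<pk_fit> Ktrans = %.4g /min, kep = %.4g /min, ve = %.4g (%s)\n",
    x$ktrans_hat, x$kep_hat, x$ve_hat, x$status))
  invisible(x)
}

# vectorised Tofts fit for a matrix of curves (voxels x times): shared kep
# grid, per-voxel parabolic refinement in log(kep), then exact ktrans
fit_tofts_many <- function(Y, times, aif = aif_params(),
                           kep_range = c(1e-3, 10), n_grid = 80) {
  cp <- population_aif(times, aif)
  m <- nrow(Y)
  lk <- seq(log(kep_range[1]), log(kep_range[2]), length.out = n_grid)
  grid <- exp(lk)
  G <- vapply(grid, function(k) tofts_conv(1, k, times, cp), numeric(length(times)))
  gg <- colSums(G * G)                       # n_grid
  num <- Y %*% G                             # m x n_grid
  yy <- rowSums(Y^2)
  rss <- yy - sweep(pmax(num, 0)^2, 2, pmax(gg, 1e-300), `/`)
  j <- max.col(-rss, ties.method = "first")
  h <- lk[2] - lk[1]
  jm <- pmax(j - 1, 1); jp <- pmin(j + 1, n_grid)
  r0 <- rss[cbind(seq_len(m), j)]
  rm <- rss[cbind(seq_len(m), jm)]
  rp <- rss[cbind(seq_len(m), jp)]
  den <- rm - 2 * r0 + rp
  shift <- ifelse(den > 1e-300 & j > 1 & j < n_grid,
                  0.5 * h * (rm - rp) / den, 0)
  kep <- exp(lk[j] + pmin(pmax(shift, -h), h))
  Gv <- tofts_conv_many(1, kep, times, cp)   # m x T unit-ktrans responses
  ktrans <- pmax(rowSums(Y * Gv) / pmax(rowSums(Gv * Gv), 1e-300), 0)
  flat <- apply(abs(Y), 1, max) < 1e-12
  ktrans[flat] <- 0
  kep[flat] <- kep_range[1]
  list(ktrans = ktrans, kep = kep,
       ve = ifelse(kep > 0, ktrans / kep, 0),
       status = ifelse(flat, "degenerate", "converged"))
}

#' Initial area under the enhancement curve
#'
#' Trapezoidal area under the tissue curve over a fixed window from
#' enhancement onset. Onset is the first sample exceeding the baseline mean
#' plus three baseline standard deviations (baseline = first `baseline_n`
#' phases); a flat curve has no detectable onset and scores 0.
#'
#' @param curve tissue concentration curve (mM).
#' @param times acquisition times (min).
#' @param window integration window from onset, minutes (default 1 = 60 s).
#' @param baseline_n number of pre-bolus phases defining the baseline.
#' @return `iauc_hat` in mM min, with a `"status"` attribute.
#' @export
compute_iauc <- function(curve, times, window = 1, baseline_n = 3) {
  stopifnot(length(curve) == length(times), window > 0)
  nb <- min(baseline_n, length(curve))
  base <- curve[seq_len(nb)]
  s <- sd(base); if (!is.finite(s)) s <- 0
  thr <- mean(base) + 3 * s + 1e-12 * max(1, abs(mean(base)))
  on <- which(curve > thr)[1]
  if (is.na(on)) return(structure(0, status = "degenerate"))
  t0 <- times[on]; t1 <- min(t0 + window, max(times))
  tt <- times[times >= t0 & times <= t1]
  cc <- curve[times >= t0 & times <= t1]
  if (t1 > max(tt)) {                        # interpolate the window end
    cc <- c(cc, approx(times, curve, t1)$y)
    tt <- c(tt, t1)
  }
  if (length(tt) < 2) return(structure(0, status = "degenerate"))
  structure(sum(diff(tt) * (head(cc, -1) + cc[-1]) / 2), status = "converged")
}

#' Compute parameter maps for every study of a cohort
#'
#' Voxel-wise T2W (identity), ADC, DKI (`D`, `K`) and Tofts
#' (`Ktrans`, `Kep`, `ve`, `iAUC`) maps, computed inside the union of the
#' subject's segmentation masks (`NA` elsewhere) on the common T2W grid.
#' Requires the DCE series for the pharmacokinetic maps.
#'
#' @param cohort `mprad_cohort`.
#' @param maps character vector of map names to compute.
#' @param bmax_adc ADC b-value cutoff.
#' @return The cohort with a `maps` element (named list of `mprad_volume`)
#'   added to each study.
#' @export
compute_cohort_maps <- function(cohort,
                                maps = c("T2W", "ADC", "D", "K", "Ktrans",
                                         "Kep", "ve", "iAUC"),
                                bmax_adc = 1500) {
  stopifnot(inherits(cohort, "mprad_cohort"))
  maps <- match.arg(maps, several.ok = TRUE)
  need_dce <- any(maps %in% c("Ktrans", "Kep", "ve", "iAUC"))
  subj_of <- vapply(cohort$segmentations, `[[`, 0, "subject_id")

  for (s in seq_along(cohort$studies)) {
    st <- cohort$studies[[s]]
    gs <- dim(st$t2w$data)
    segs <- cohort$segmentations[subj_of == st$subject_id]
    un <- Reduce(`|`, lapply(segs, function(g) g$mask$data),
                 array(FALSE, gs))
    vox <- which(un)
    out <- list()
    mkvol <- function(vals) {
      a <- array(NA_real_, gs); a[vox] <- vals
      volume(a, st$t2w$spacing, st$t2w$origin)
    }
    if ("T2W" %in% maps) out$T2W <- st$t2w
    if (any(maps %in% c("ADC", "D", "K"))) {
      if (is.null(st$dwi)) stop("study has no DWI series; cannot compute ADC/DKI maps")
      nb <- length(st$bvals)
      S <- matrix(st$dwi[outer(vox, (seq_len(nb) - 1) * prod(gs), `+`)],
                  length(vox), nb)
      if ("ADC" %in% maps) {
        keep <- st$bvals <= bmax_adc
        b <- st$bvals[keep]
        ok <- rowSums(S[, keep, drop = FALSE] <= 0) == 0
        adc <- numeric(length(vox))
        if (any(ok)) {
          L <- log(S[ok, keep, drop = FALSE])
          bc <- b - mean(b)
          adc[ok] <- pmax(-(L %*% bc) / sum(bc^2), 0)
        }
        if (any(!ok))
          adc[!ok] <- vapply(which(!ok), function(i)
            as.numeric(fit_adc(S[i, ], st$bvals, bmax_adc)), 0)
        out$ADC <- mkvol(adc)
      }
      if (any(c("D", "K") %in% maps)) {
        dk <- vapply(seq_len(length(vox)), function(i) {
          f <- fit_dki(S[i, ], st$bvals)
          c(f$d_hat, f$k_hat)
        }, numeric(2))
        if ("D" %in% maps) out$D <- mkvol(dk[1, ])
        if ("K" %in% maps) out$K <- mkvol(dk[2, ])
      }
    }
    if (need_dce) {
      if (is.null(st$dce))
        stop(sprintf("study has no DCE series; cannot compute maps: %s",
                     paste(intersect(maps, c("Ktrans", "Kep", "ve", "iAUC")),
                           collapse = ", ")))
      nt <- length(st$dce_times)
      Y <- matrix(st$dce[outer(vox, (seq_len(nt) - 1) * prod(gs), `+`)],
                  length(vox), nt)
      if (any(c("Ktrans", "Kep", "ve") %in% maps)) {
        pk <- fit_tofts_many(Y, st$dce_times, cohort$spec$aif)
        if ("Ktrans" %in% maps) out$Ktrans <- mkvol(pk$ktrans)
        if ("Kep" %in% maps) out$Kep <- mkvol(pk$kep)
        if ("ve" %in% maps) out$ve <- mkvol(pk$ve)
      }
      if ("iAUC" %in% maps)
        out$iAUC <- mkvol(vapply(seq_len(length(vox)), function(i)
          as.numeric(compute_iauc(Y[i, ], st$dce_times)), 0))
    }
    cohort$studies[[s]]$maps <- out
  }
  cohort
}
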