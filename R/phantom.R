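#' @importFrom stats rnorm runif optimize median sd quantile setNames
NULL

# run code under a temporary RNG state; NULL seed = use current stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Ground-truth tissue parameters for one class
#'
#' Generative per-class parameters of the phantom: the diffusion-kurtosis pair
#' (`d`, `k`), the Tofts pair (`ktrans`, `kep`, with `ve = ktrans / kep`), the
#' baseline DWI signal `s0` and the T2W intensity distribution
#' (`t2w_mean`, `t2w_sd`).
#'
#' @param s0 baseline (b = 0) DWI signal, arbitrary units, > 0.
#' @param d diffusion coefficient D in mm^2/s, > 0.
#' @param k diffusional kurtosis K (dimensionless), >= 0.
#' @param ktrans volume transfer constant K^trans in 1/min, >= 0.
#' @param kep rate constant k_ep in 1/min, > 0.
#' @param t2w_mean,t2w_sd T2W intensity mean and spread, arbitrary units.
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(s0 = 1000, d = 1.55e-3, k = 0.60,
                          ktrans = 0.12, kep = 0.55,
                          t2w_mean = 130, t2w_sd = 18) {
  stopifnot(s0 > 0, d > 0, k >= 0, ktrans >= 0, kep > 0, t2w_sd >= 0)
  ve <- ktrans / kep
  if (ve > 1) stop("ve = ktrans/kep must lie in (0, 1]")
  structure(list(s0 = s0, d = d, k = k, ktrans = ktrans, kep = kep, ve = ve,
                 t2w_mean = t2w_mean, t2w_sd = t2w_sd),
            class = "tissue_params")
}

#' Default class parameters
#'
#' Class means for the two tissue classes of the phantom, chosen once from the
#' prostate DKI / DCE literature: PI-RADS 4-5-like lesions have restricted,
#' more non-Gaussian diffusion (lower D, higher K), faster contrast transfer
#' (higher K^trans) and lower T2W signal than healthy peripheral-zone tissue.
#'
#' @return A `tissue_params` object.
#' @export
lesion_tissue_params <- function() {
  tissue_params(s0 = 1000, d = 0.90e-3, k = 1.05, ktrans = 0.35, kep = 1.00,
                t2w_mean = 90, t2w_sd = 14)
}

#' @rdname lesion_tissue_params
#' @export
healthy_tissue_params <- function() {
  tissue_params(s0 = 1000, d = 1.55e-3, k = 0.60, ktrans = 0.12, kep = 0.55,
                t2w_mean = 130, t2w_sd = 18)
}

# noiseless diffusion-kurtosis signal; vectorised over s0/d/k or b
dki_signal <- function(s0, d, k, b) {
  s0 * exp(-b * d + (b^2 * d^2 * k) / 6)
}

# magnitude (Rician) corruption of a noiseless signal
rician <- function(s, sd) {
  if (sd == 0) return(s)
  sqrt((s + rnorm(length(s), 0, sd))^2 + rnorm(length(s), 0, sd)^2)
}

#' Simulate a diffusion-kurtosis decay over b-values
#'
#' Forward DKI model `S(b) = S0 exp(-b D + b^2 D^2 K / 6)`, optionally
#' corrupted by Rician noise (magnitude of a complex Gaussian perturbation),
#' the noise law of magnitude MR images.
#'
#' @param params `tissue_params`.
#' @param bvals non-negative b-values in s/mm^2.
#' @param noise_sd Rician noise scale (0 = exact signal).
#' @param seed optional integer seed (local to this call).
#' @return Numeric vector of signals, one per b-value.
#' @export
simulate_dwi_signal <- function(params, bvals, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(params, "tissue_params"), noise_sd >= 0)
  if (any(bvals < 0)) stop("b-values must be non-negative")
  s <- dki_signal(params$s0, params$d, params$k, bvals)
  with_seed(seed, rician(s, noise_sd))
}

#' Bi-exponential population arterial input function
#'
#' Parameters of the plasma contrast concentration curve
#' `Cp(t) = dose * (a1 exp(-m1 (t - onset)) + a2 exp(-m2 (t - onset)))` for
#' `t >= onset`, zero before. Defaults are the classic Weinmann population
#' constants with a 0.1 mmol/kg dose; the bolus arrival defaults to the end of
#' the first dynamic phase (0.15 min).
#'
#' @param dose amplitude scale (mmol/kg body weight).
#' @param a1,a2 compartment amplitudes (kg/L).
#' @param m1,m2 decay rates (1/min).
#' @param onset bolus arrival time (min).
#' @return An object of class `aif_params`.
#' @export
aif_params <- function(dose = 0.1, a1 = 3.99, a2 = 4.78,
                       m1 = 0.144, m2 = 0.0111, onset = 0.15) {
  stopifnot(dose >= 0, a1 >= 0, a2 >= 0, m1 >= 0, m2 >= 0, onset >= 0)
  structure(list(dose = dose, a1 = a1, a2 = a2, m1 = m1, m2 = m2,
                 onset = onset), class = "aif_params")
}

#' Evaluate the population AIF
#'
#' @param times acquisition times in minutes, sorted ascending.
#' @param aif `aif_params`.
#' @return Plasma concentration (mM) at each time.
#' @export
population_aif <- function(times, aif = aif_params()) {
  stopifnot(inherits(aif, "aif_params"))
  if (is.unsorted(times)) stop("`times` must be sorted")
  tt <- times - aif$onset
  cp <- aif$dose * (aif$a1 * exp(-aif$m1 * tt) + aif$a2 * exp(-aif$m2 * tt))
  cp[tt < 0] <- 0
  cp
}

# exact convolution of a piecewise-linear Cp with ktrans * exp(-kep t).
# Linear interpolation of Cp inside each interval makes the per-interval
# integral closed-form, so the recursion is exact for piecewise-linear input.
tofts_conv <- function(ktrans, kep, times, cp) {
  n <- length(times)
  ct <- numeric(n)
  if (n < 2) return(ct)
  for (i in seq_len(n - 1)) {
    dt <- times[i + 1] - times[i]
    e <- exp(-kep * dt)
    a <- (1 - e) / kep
    bcoef <- a - (1 - e * (1 + kep * dt)) / (kep^2 * dt)
    ct[i + 1] <- ct[i] * e + cp[i] * (a - bcoef) + cp[i + 1] * bcoef
  }
  ktrans * ct
}

# vectorised over voxels: ktrans, kep vectors -> voxels x times matrix
tofts_conv_many <- function(ktrans, kep, times, cp) {
  m <- length(kep); n <- length(times)
  ct <- matrix(0, m, n)
  if (n < 2) return(ct * ktrans)
  for (i in seq_len(n - 1)) {
    dt <- times[i + 1] - times[i]
    e <- exp(-kep * dt)
    a <- (1 - e) / kep
    bcoef <- a - (1 - e * (1 + kep * dt)) / (kep^2 * dt)
    ct[, i + 1] <- ct[, i] * e + cp[i] * (a - bcoef) + cp[i + 1] * bcoef
  }
  ct * ktrans
}

#' Simulate a Tofts tissue concentration curve
#'
#' Standard Tofts model: `Ct(t) = Ktrans * int_0^t Cp(tau) exp(-kep (t - tau))
#' dtau`, computed by exact convolution of the piecewise-linear AIF with the
#' exponential kernel on the acquisition grid, plus additive Gaussian noise.
#'
#' @param params `tissue_params` (uses `ktrans`, `kep`).
#' @param aif `aif_params`.
#' @param times acquisition times (min), sorted.
#' @param noise_sd Gaussian noise sd on the concentration scale (mM).
#' @param seed optional integer seed (local to this call).
#' @return Numeric vector of tissue concentrations (mM).
#' @export
simulate_dce_curve <- function(params, aif = aif_params(), times,
                               noise_sd = 0, seed = NULL) {
  stopifnot(inherits(params, "tissue_params"), noise_sd >= 0)
  if (params$kep <= 0) stop("kep must be positive")
  cp <- population_aif(times, aif)
  ct <- tofts_conv(params$ktrans, params$kep, times, cp)
  with_seed(seed, ct + rnorm(length(ct), 0, noise_sd))
}

#' One segmentation (3D VOI or derived 2D ROI)
#'
#' @param subject_id subject identifier.
#' @param label `"lesion"` or `"healthy"`.
#' @param mask logical `mprad_volume`, non-empty.
#' @param roi_dim `"3D"` or `"2D"`.
#' @param slice_index axial slice index, required iff `roi_dim = "2D"`.
#' @param voi_id optional unique id.
#' @return An object of class `segmentation_record`.
#' @export
segmentation_record <- function(subject_id, label, mask, roi_dim = "3D",
                                slice_index = NULL, voi_id = NULL) {
  label <- match.arg(label, c("lesion", "healthy"))
  roi_dim <- match.arg(roi_dim, c("3D", "2D"))
  stopifnot(is_volume(mask), is.logical(mask$data))
  if (!any(mask$data)) stop("segmentation mask is empty")
  if (roi_dim == "2D") {
    slices <- unique(which(mask$data, arr.ind = TRUE)[, 3])
    if (length(slices) != 1L)
      stop("2D segmentation must live on a single axial slice")
    if (is.null(slice_index)) slice_index <- slices
    stopifnot(slice_index == slices)
  }
  structure(list(subject_id = subject_id, label = label, mask = mask,
                 roi_dim = roi_dim, slice_index = slice_index,
                 voi_id = voi_id), class = "segmentation_record")
}

#' Specification of a synthetic multiparametric cohort
#'
#' The stated world of the phantom: cohort bookkeeping mirrors the clinical
#' dataset the analysis was designed for (65 subjects, 69 lesion and 49
#' healthy-tissue VOIs), the DWI b-value scheme is
#' `0, 250, 500 | 1000, 1500 | 2000, 2500` s/mm^2 with 4/6/8 averages per
#' group (emulated as noise sd divided by sqrt(averages)), and the dynamic
#' series has 60 phases at 9 s. The grid is a desk-scale stand-in for a
#' prostate field of view.
#'
#' @param n_subjects number of subjects.
#' @param n_lesion_vois,n_ht_vois VOIs per class (both >= 1).
#' @param lesion_params,ht_params class `tissue_params`.
#' @param bvals b-values (s/mm^2): non-negative, strictly increasing, with 0.
#' @param averages signal averages per b-value (noise sd is divided by their
#'   square root).
#' @param dce_times dynamic acquisition times (min), strictly increasing, or
#'   `NULL` to omit the DCE series.
#' @param aif `aif_params` driving the Tofts simulation.
#' @param noise_sd_dwi Rician noise scale at 1 average (signal units).
#' @param noise_sd_dce Gaussian concentration noise sd (mM).
#' @param voi_semiaxes range (voxels) of the random ellipsoid semi-axes.
#' @param grid_shape,spacing grid size (voxels) and spacing (mm).
#' @param between_voi_cv,within_voi_cv lognormal coefficients of variation of
#'   the per-VOI parameter draw and the within-VOI voxel jitter.
#' @param seed integer seed making the cohort reproducible.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 65, n_lesion_vois = 69, n_ht_vois = 49,
                        lesion_params = lesion_tissue_params(),
                        ht_params = healthy_tissue_params(),
                        bvals = c(0, 250, 500, 1000, 1500, 2000, 2500),
                        averages = c(4, 4, 4, 6, 6, 8, 8),
                        dce_times = seq(0, by = 9 / 60, length.out = 60),
                        aif = aif_params(),
                        noise_sd_dwi = 25, noise_sd_dce = 0.02,
                        voi_semiaxes = c(2.2, 4.5),
                        grid_shape = c(32, 32, 16), spacing = c(2, 2, 3),
                        between_voi_cv = 0.08, within_voi_cv = 0.05,
                        seed = 1L) {
  stopifnot(n_subjects >= 1, n_lesion_vois >= 1, n_ht_vois >= 1,
            inherits(lesion_params, "tissue_params"),
            inherits(ht_params, "tissue_params"),
            inherits(aif, "aif_params"),
            noise_sd_dwi >= 0, noise_sd_dce >= 0,
            length(voi_semiaxes) == 2, voi_semiaxes[1] > 0,
            voi_semiaxes[2] >= voi_semiaxes[1],
            length(grid_shape) == 3, all(grid_shape >= 4),
            length(averages) == length(bvals), all(averages >= 1))
  if (n_lesion_vois + n_ht_vois < 2)
    stop("at least two VOIs are required")
  if (any(bvals < 0) || is.unsorted(bvals, strictly = TRUE) || !(0 %in% bvals))
    stop("`bvals` must be non-negative, strictly increasing and contain 0")
  if (!is.null(dce_times) && is.unsorted(dce_times, strictly = TRUE))
    stop("`dce_times` must be strictly increasing")
  structure(list(n_subjects = n_subjects, n_lesion_vois = n_lesion_vois,
                 n_ht_vois = n_ht_vois, lesion_params = lesion_params,
                 ht_params = ht_params, bvals = bvals, averages = averages,
                 dce_times = dce_times, aif = aif,
                 noise_sd_dwi = noise_sd_dwi, noise_sd_dce = noise_sd_dce,
                 voi_semiaxes = voi_semiaxes, grid_shape = grid_shape,
                 spacing = spacing, between_voi_cv = between_voi_cv,
                 within_voi_cv = within_voi_cv, seed = seed),
            class = "cohort_spec")
}

# ellipsoid mask centred at `centre` with semi-axes `ax` (voxel units)
ellipsoid_mask <- function(grid_shape, centre, ax) {
  x <- (seq_len(grid_shape[1]) - centre[1]) / ax[1]
  y <- (seq_len(grid_shape[2]) - centre[2]) / ax[2]
  z <- (seq_len(grid_shape[3]) - centre[3]) / ax[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
}

# multiplicative lognormal jitter with coefficient of variation cv
ln_jitter <- function(n, cv) if (cv <= 0) rep(1, n) else exp(rnorm(n, 0, cv))

#' Generate a synthetic multiparametric cohort
#'
#' Draws per-VOI tissue parameters around the class means, places
#' non-overlapping ellipsoidal VOIs on each subject's grid, simulates T2W,
#' multi-b DWI (Rician noise) and dynamic DCE (Gaussian noise) volumes, and
#' returns the studies together with all segmentation records and a ground
#' truth table for recovery tests. Identical spec (including seed) gives a
#' bit-identical cohort.
#'
#' @param spec `cohort_spec`.
#' @return An object of class `mprad_cohort`: list with `spec`, `studies`
#'   (per subject), `segmentations` (one `segmentation_record` per VOI) and
#'   `truth` (data frame of per-VOI generative parameters).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n_voi <- spec$n_lesion_vois + spec$n_ht_vois
  labels <- sample(c(rep("lesion", spec$n_lesion_vois),
                     rep("healthy", spec$n_ht_vois)))
  subj <- rep(seq_len(spec$n_subjects), length.out = n_voi)
  gs <- spec$grid_shape
  hp <- spec$ht_params; lp <- spec$lesion_params

  studies <- vector("list", spec$n_subjects)
  segmentations <- vector("list", n_voi)
  truth <- vector("list", n_voi)
  cp <- if (!is.null(spec$dce_times)) population_aif(spec$dce_times, spec$aif)

  # background tissue behaves like unjittered healthy tissue
  bg_ct <- if (!is.null(spec$dce_times))
    tofts_conv(hp$ktrans, hp$kep, spec$dce_times, cp)

  voi_idx <- 0
  for (s in seq_len(spec$n_subjects)) {
    my_vois <- which(subj == s)
    occupied <- array(FALSE, gs)
    masks <- list()
    # ground-truth parameter maps start at the healthy background
    pm <- list(s0 = array(hp$s0, gs), d = array(hp$d, gs),
               k = array(hp$k, gs), ktrans = array(hp$ktrans, gs),
               kep = array(hp$kep, gs))
    t2w <- array(rnorm(prod(gs), hp$t2w_mean, hp$t2w_sd), gs)

    for (v in my_vois) {
      cls <- if (labels[v] == "lesion") lp else hp
      placed <- FALSE
      for (try in 1:200) {
        ax <- runif(3, spec$voi_semiaxes[1], spec$voi_semiaxes[2])
        m <- ceiling(ax)
        if (any(gs - 2 * m - 1 < 1))
          stop("VOI semi-axes too large for the grid: cannot place VOI")
        ctr <- c(sample(seq(m[1] + 1, gs[1] - m[1]), 1),
                 sample(seq(m[2] + 1, gs[2] - m[2]), 1),
                 sample(seq(m[3] + 1, gs[3] - m[3]), 1))
        mask <- ellipsoid_mask(gs, ctr, ax)
        if (!any(mask & occupied)) { placed <- TRUE; break }
      }
      if (!placed)
        stop(sprintf("could not place VOI %d on subject %d without overlap",
                     v, s))
      occupied <- occupied | mask
      nv <- sum(mask)

      jit <- exp(rnorm(5, 0, spec$between_voi_cv))
      par_voi <- list(d = cls$d * jit[1], k = cls$k * jit[2],
                      ktrans = cls$ktrans * jit[3], kep = cls$kep * jit[4],
                      t2w_mean = cls$t2w_mean * jit[5])
      pm$s0[mask] <- cls$s0
      pm$d[mask] <- par_voi$d * ln_jitter(nv, spec$within_voi_cv)
      pm$k[mask] <- par_voi$k * ln_jitter(nv, spec$within_voi_cv)
      pm$ktrans[mask] <- par_voi$ktrans * ln_jitter(nv, spec$within_voi_cv)
      pm$kep[mask] <- par_voi$kep * ln_jitter(nv, spec$within_voi_cv)
      t2w[mask] <- rnorm(nv, par_voi$t2w_mean, cls$t2w_sd)

      voi_idx <- voi_idx + 1
      segmentations[[voi_idx]] <- segmentation_record(
        subject_id = s, label = labels[v],
        mask = volume(mask, spec$spacing), voi_id = voi_idx)
      truth[[voi_idx]] <- data.frame(
        voi_id = voi_idx, subject_id = s, label = labels[v],
        n_voxels = nv, d = par_voi$d, k = par_voi$k,
        ktrans = par_voi$ktrans, kep = par_voi$kep,
        ve = par_voi$ktrans / par_voi$kep, t2w_mean = par_voi$t2w_mean)
    }

    # DWI stack: Rician noise, per-b sd reduced by sqrt(averages)
    dwi <- array(0, c(gs, length(spec$bvals)))
    for (bi in seq_along(spec$bvals)) {
      sb <- dki_signal(pm$s0, pm$d, pm$k, spec$bvals[bi])
      dwi[, , , bi] <- rician(sb, spec$noise_sd_dwi / sqrt(spec$averages[bi]))
    }

    # DCE stack: shared background curve, per-voxel curves inside VOIs
    dce <- NULL
    if (!is.null(spec$dce_times)) {
      nt <- length(spec$dce_times)
      dce <- array(rep(bg_ct, each = prod(gs)), c(gs, nt))
      if (any(occupied)) {
        vox <- which(occupied)
        ct <- tofts_conv_many(pm$ktrans[vox], pm$kep[vox], spec$dce_times, cp)
        for (ti in seq_len(nt))
          dce[vox + (ti - 1) * prod(gs)] <- ct[, ti]
      }
      if (spec$noise_sd_dce > 0)
        for (ti in seq_len(nt)) {
          sl <- seq_len(prod(gs)) + (ti - 1) * prod(gs)
          dce[sl] <- dce[sl] + rnorm(prod(gs), 0, spec$noise_sd_dce)
        }
    }

    studies[[s]] <- structure(
      list(subject_id = s,
           t2w = volume(t2w, spec$spacing),
           bvals = spec$bvals, dwi = dwi,
           dce_times = spec$dce_times, dce = dce,
           truth = lapply(pm, function(a) volume(a, spec$spacing))),
      class = "mprad_study")
  }

  structure(list(spec = spec, studies = studies,
                 segmentations = segmentations,
                 truth = do.call(rbind, truth)),
            class = "mprad_cohort")
}

#' @export
print.mprad_cohort <- function(x, ...) {
  tab <- table(vapply(x$segmentations, `[[`, "", "label"))
  cat(sprintf("<mprad_cohort> %d subjects, %d segmentations (%s)\n",
              length(x$studies), length(x$segmentations),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}
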