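# shared fixtures and naive reference implementations

.fixtures <- new.env()

# small cohort with maps, generated once per test run
small_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    spec <- cohort_spec(n_subjects = 6, n_lesion_vois = 7, n_ht_vois = 6,
                        grid_shape = c(20, 20, 10), voi_semiaxes = c(1.8, 3),
                        seed = 42)
    .fixtures$cohort <- compute_cohort_maps(generate_cohort(spec))
  }
  .fixtures$cohort
}

# a region object built directly from a value vector (single-slice mask)
region_from_values <- function(x) {
  n <- length(x)
  a <- array(0, c(n, 1, 1))
  a[, 1, 1] <- x
  m <- array(TRUE, c(n, 1, 1))
  normalize_intensities(volume(a), segmentation_record(1, "lesion",
                                                       volume(m)))
}

# independent first-order reference: explicit formulas, cut()-based binning
naive_first_order <- function(x, lo, hi, nbins = 256) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  if (hi > lo) {
    br <- seq(lo, hi, length.out = nbins + 1)
    p <- as.vector(table(cut(x, br, right = FALSE, include.lowest = TRUE))) / n
    p <- p[p > 0]
    entropy <- -sum(p * log2(p))
    uniformity <- sum(p^2)
  } else {
    entropy <- 0; uniformity <- 1
  }
  c(energy = sum(x^2), entropy = entropy,
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    max = max(x), mean = mu, mad = sum(abs(x - mu)) / n,
    median = median(x), min = min(x), rms = sqrt(sum(x^2) / n),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0, std = sqrt(m2),
    uniformity = uniformity, variance = m2)
}

# brute-force GLCM: enumerate every voxel and all neighbour displacements
# (full 26 or 8 set, so both orderings are counted without symmetrization)
naive_glcm <- function(q, mask, levels) {
  d <- dim(q)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (length(unique(which(mask, arr.ind = TRUE)[, 3])) <= 1)
    offs <- offs[offs$dz == 0, ]
  C <- matrix(0, levels, levels)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (!mask[x, y, z]) next
    for (r in seq_len(nrow(offs))) {
      x2 <- x + offs$dx[r]; y2 <- y + offs$dy[r]; z2 <- z + offs$dz[r]
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] ||
          z2 < 1 || z2 > d[3]) next
      if (!mask[x2, y2, z2]) next
      C[q[x, y, z], q[x2, y2, z2]] <- C[q[x, y, z], q[x2, y2, z2]] + 1
    }
  }
  if (sum(C) == 0) return(structure(C, degenerate = TRUE))
  C / sum(C)
}

# direct double-loop Haralick reference
naive_glcm_features <- function(P) {
  L <- nrow(P)
  e <- ct <- h <- dis <- ac <- vr <- ent <- 0
  mui <- muj <- 0
  for (i in 1:L) for (j in 1:L) {
    mui <- mui + i * P[i, j]; muj <- muj + j * P[i, j]
  }
  s2i <- s2j <- corr_num <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    e <- e + p^2
    ct <- ct + (i - j)^2 * p
    if (p > 0) ent <- ent - p * log2(p)
    h <- h + p / (1 + abs(i - j))
    dis <- dis + abs(i - j) * p
    ac <- ac + i * j * p
    vr <- vr + (i - mui)^2 * p
    s2i <- s2i + (i - mui)^2 * p
    s2j <- s2j + (j - muj)^2 * p
    corr_num <- corr_num + (i - mui) * (j - muj) * p
  }
  sa <- 0
  for (k in 2:(2 * L)) {
    pk <- 0
    for (i in 1:L) for (j in 1:L) if (i + j == k) pk <- pk + P[i, j]
    sa <- sa + k * pk
  }
  c(energy = e, contrast = ct, entropy = ent, homogeneity = h,
    correlation = if (s2i > 0 && s2j > 0) corr_num / sqrt(s2i * s2j) else 0,
    sum_average = sa, variance = vr, dissimilarity = dis,
    autocorrelation = ac)
}

# random in-mask region + quantization, for oracle-equivalence sweeps
random_region <- function(seed, shape = c(6, 6, 4)) {
  set.seed(seed)
  a <- array(rnorm(prod(shape), 100, 20), shape)
  m <- array(runif(prod(shape)) < 0.7, shape)
  m[sample(prod(shape), 1)] <- TRUE            # never empty
  seg <- segmentation_record(1, "lesion", volume(m))
  list(vol = volume(a), seg = seg,
       region = normalize_intensities(volume(a), seg))
}
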