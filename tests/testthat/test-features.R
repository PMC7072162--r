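test_that("first-order features match direct arithmetic", {
  f <- first_order_features(region_from_values(1:8))
  expect_equal(unname(f["mean"]), 4.5)
  expect_equal(unname(f["variance"]), 5.25)
  expect_equal(unname(f["mad"]), 2)
  expect_equal(unname(f["energy"]), 204)
  expect_equal(unname(f["rms"]), sqrt(25.5))
  expect_equal(unname(f["median"]), 4.5)
  expect_identical(unname(f[c("min", "max")]), c(1, 8))

  # degenerate constant region
  fc <- first_order_features(region_from_values(rep(3, 20)))
  expect_identical(unname(fc[c("variance", "entropy", "skewness",
                               "kurtosis")]), rep(0, 4))
  expect_identical(unname(fc["uniformity"]), 1)
  expect_identical(unname(fc["max"]), unname(fc["min"]))

  # two equal-mass histogram bins: entropy one bit, uniformity one half
  f2 <- first_order_features(region_from_values(rep(c(0, 1), 50)))
  expect_equal(unname(f2["entropy"]), 1)
  expect_equal(unname(f2["uniformity"]), 0.5)

  expect_identical(names(f), mprad:::first_order_names)
  expect_length(f, 13)
})

test_that("first-order features match the naive reference on random regions", {
  for (s in 1:8) {
    r <- random_region(s)$region
    got <- first_order_features(r)
    want <- naive_first_order(r$values, r$lo, r$hi)
    expect_equal(got, want[names(got)], tolerance = 1e-12)
  }
})

test_that("GLCM accumulation matches brute-force pair enumeration", {
  # constant region: a single co-occurrence level
  q1 <- array(1L, c(3, 3, 2)); m1 <- array(TRUE, c(3, 3, 2))
  P1 <- build_glcm(q1, m1, levels = 4)
  expect_identical(P1[1, 1], 1)
  expect_identical(sum(P1), 1)

  # 2x2 single-slice slab, hand-enumerated over the 4 in-plane directions:
  # pairs 1-1 x3 and 1-2 x3, each counted in both orders
  q2 <- array(c(1L, 1L, 1L, 2L), c(2, 2, 1)); m2 <- array(TRUE, c(2, 2, 1))
  P2 <- build_glcm(q2, m2, levels = 2)
  expect_equal(P2, matrix(c(0.5, 0.25, 0.25, 0), 2, 2))
  expect_equal(P2, naive_glcm(q2, m2, 2))

  # random 5x5x5 region equals the triple-loop oracle exactly
  set.seed(14)
  q3 <- array(sample(1:6, 125, replace = TRUE), c(5, 5, 5))
  m3 <- array(runif(125) < 0.8, c(5, 5, 5)); m3[1] <- TRUE
  P3 <- build_glcm(q3, m3, levels = 6)
  expect_identical(P3, naive_glcm(q3, m3, 6))
  expect_identical(P3, t(P3))

  # single voxel: no pairs, degenerate by convention
  m4 <- array(FALSE, c(3, 3, 3)); m4[2, 2, 2] <- TRUE
  P4 <- build_glcm(array(1L, c(3, 3, 3)), m4, levels = 2)
  expect_true(attr(P4, "degenerate"))
  g4 <- glcm_features(P4)
  expect_identical(unname(g4["energy"]), 1)
  expect_identical(unname(g4["homogeneity"]), 1)
  expect_identical(unname(g4["contrast"]), 0)
})

test_that("GLCM features match direct summation", {
  # point mass
  P <- matrix(0, 3, 3); P[1, 1] <- 1
  g <- glcm_features(P)
  expect_identical(unname(g[c("energy", "contrast", "entropy", "homogeneity",
                              "sum_average", "autocorrelation")]),
                   c(1, 0, 0, 1, 2, 1))
  # uniform matrix
  L <- 8
  gu <- glcm_features(matrix(1 / L^2, L, L))
  expect_equal(unname(gu["energy"]), 1 / L^2)
  expect_equal(unname(gu["entropy"]), 2 * log2(L))

  # asymmetric hand-set matrix against the double-loop reference
  Ph <- matrix(c(0.2, 0.1, 0, 0.1, 0.25, 0.05, 0, 0.05, 0.25), 3, 3)
  expect_equal(glcm_features(Ph), naive_glcm_features(Ph), tolerance = 1e-12)

  # properties on random region GLCMs
  for (s in 1:5) {
    r <- random_region(s + 50)
    qq <- quantize_region(r$region, 16)
    P <- build_glcm(qq$qvol, r$seg$mask$data, 16)
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_identical(P, t(P))
    expect_lte(glcm_features(P)["entropy"], 2 * log2(16))
    expect_gt(glcm_features(P)["energy"], 0)
  }
})

test_that("feature tables carry the catalog of each classification task", {
  co <- small_cohort()
  std <- extract_feature_table(co, "std3D")
  expect_length(feature_columns(std), 44)
  expect_identical(nrow(std), 13L)
  expect_setequal(unique(std$label), c(0, 1))

  adv3 <- extract_feature_table(co, "adv3D")
  expect_length(feature_columns(adv3), 104)
  expect_true(all(grepl("\\.first\\.", feature_columns(adv3))))

  adv2 <- extract_feature_table(co, "adv2D")
  expect_length(feature_columns(adv2), 104)
  # 2D ROIs are sub-regions of the VOIs: tables must differ
  expect_false(isTRUE(all.equal(adv3$ADC.first.mean, adv2$ADC.first.mean)))

  # a study without DCE maps fails loudly, naming the missing maps
  co2 <- generate_cohort(cohort_spec(
    n_subjects = 2, n_lesion_vois = 2, n_ht_vois = 2,
    grid_shape = c(16, 16, 8), voi_semiaxes = c(1.6, 2.4),
    dce_times = NULL, seed = 2))
  co2 <- compute_cohort_maps(co2, maps = c("T2W", "ADC"))
  expect_error(extract_feature_table(co2, "adv3D"), "Ktrans")
  expect_error(compute_cohort_maps(co2, maps = "Ktrans"), "no DCE")
})

test_that("histogram features are invariant to positive affine rescaling", {
  co <- small_cohort()
  seg <- co$segmentations[[1]]
  st <- co$studies[[seg$subject_id]]
  t2w <- st$maps$T2W
  t2w_aff <- volume(3.5 * t2w$data + 120, t2w$spacing, t2w$origin)
  r1 <- normalize_intensities(t2w, seg)
  r2 <- normalize_intensities(t2w_aff, seg)
  f1 <- first_order_features(r1); f2 <- first_order_features(r2)
  inv <- c("entropy", "uniformity", "skewness", "kurtosis")
  expect_equal(f1[inv], f2[inv], tolerance = 1e-9)
  expect_equal(unname(f2["mean"]), 3.5 * unname(f1["mean"]) + 120,
               tolerance = 1e-9)
  expect_equal(unname(f2["std"]), 3.5 * unname(f1["std"]), tolerance = 1e-9)
  # quantized levels, hence the GLCM, are unchanged too
  q1 <- quantize_region(r1, 32); q2 <- quantize_region(r2, 32)
  expect_identical(q1$qvals, q2$qvals)
})
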