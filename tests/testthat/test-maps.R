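paper_bvals <- c(0, 250, 500, 1000, 1500, 2000, 2500)

test_that("ADC fit recovers monoexponential decay and flags degeneracy", {
  b5 <- c(0, 250, 500, 1000, 1500)
  s <- 900 * exp(-b5 * 1.2e-3)
  expect_equal(as.numeric(fit_adc(s, b5)), 1.2e-3, tolerance = 1e-12)
  # constant signal: zero slope
  f <- fit_adc(rep(500, 5), b5)
  expect_identical(as.numeric(f), 0)
  # kurtosis inflates high-b signal, so the restricted log-linear ADC
  # underestimates the generating D
  sk <- simulate_dwi_signal(tissue_params(d = 1.0e-3, k = 1.2), paper_bvals)
  expect_lt(as.numeric(fit_adc(sk, paper_bvals)), 1.0e-3)
  # non-positive signals are excluded; < 2 left is degenerate
  f2 <- fit_adc(c(100, -1, 0), c(0, 500, 1000))
  expect_identical(attr(f2, "status"), "degenerate")
})

test_that("DKI fit recovers noiseless parameters and nests the ADC model", {
  s <- simulate_dwi_signal(tissue_params(s0 = 1000, d = 1.0e-3, k = 1.2),
                           paper_bvals)
  f <- fit_dki(s, paper_bvals)
  expect_equal(f$d_hat, 1.0e-3, tolerance = 1e-6)
  expect_equal(f$k_hat, 1.2, tolerance = 1e-6)
  expect_equal(f$s0_hat, 1000, tolerance = 1e-6)
  expect_identical(f$status, "converged")

  # K = 0 generator: nested-model consistency with the ADC route
  b5 <- c(0, 250, 500, 1000, 1500)
  s0k <- 1000 * exp(-b5 * 1.4e-3)
  f0 <- fit_dki(s0k, b5)
  expect_lt(f0$k_hat, 1e-5)
  expect_lt(abs(f0$d_hat - f0$adc_hat), 1e-9)

  fc <- fit_dki(rep(800, 7), paper_bvals)
  expect_identical(fc$status, "degenerate")
  expect_identical(fc$d_hat, 0)
})

test_that("Tofts fit recovers noiseless curves within 1%", {
  times <- seq(0, by = 9 / 60, length.out = 60)   # 60 phases at 9 s
  aif <- aif_params()
  cv <- simulate_dce_curve(tissue_params(ktrans = 0.25, kep = 0.625),
                           aif, times)
  f <- fit_tofts(cv, times, aif)
  expect_equal(f$ktrans_hat, 0.25, tolerance = 0.01)
  expect_equal(f$kep_hat, 0.625, tolerance = 0.01)
  expect_equal(f$ve_hat, 0.4, tolerance = 0.01)
  expect_identical(f$ve_hat, f$ktrans_hat / f$kep_hat)

  fz <- fit_tofts(rep(0, 60), times, aif)
  expect_identical(fz$ktrans_hat, 0)
  expect_identical(fz$status, "degenerate")
  expect_identical(fz$iauc_hat, 0)
})

test_that("vectorised Tofts map fitting agrees with the scalar fit", {
  times <- seq(0, by = 9 / 60, length.out = 60)
  aif <- aif_params()
  kt <- c(0.05, 0.15, 0.35); kp <- c(0.3, 0.9, 1.6)
  Y <- t(vapply(1:3, function(i)
    simulate_dce_curve(tissue_params(ktrans = kt[i], kep = kp[i]),
                       aif, times), numeric(60)))
  pk <- mprad:::fit_tofts_many(Y, times, aif)
  expect_equal(pk$ktrans, kt, tolerance = 5e-3)
  expect_equal(pk$kep, kp, tolerance = 5e-3)
})

test_that("iAUC integrates a 60 s window from enhancement onset", {
  times <- seq(0, by = 9 / 60, length.out = 60)
  expect_identical(as.numeric(compute_iauc(rep(0, 60), times)), 0)
  expect_identical(attr(compute_iauc(rep(0, 60), times), "status"),
                   "degenerate")
  # step to a 1 mM plateau: rectangle of area 1 mM min over the 60 s window
  step <- c(rep(0, 5), rep(1, 55))
  expect_equal(as.numeric(compute_iauc(step, times)), 1.0, tolerance = 1e-12)
  # linearity in curve amplitude
  cv <- simulate_dce_curve(tissue_params(ktrans = 0.2, kep = 0.6),
                           times = times)
  expect_equal(as.numeric(compute_iauc(3 * cv, times)),
               3 * as.numeric(compute_iauc(cv, times)), tolerance = 1e-12)
})

test_that("grid resampling is exact where exactness is required", {
  v <- volume(array(rnorm(4 * 5 * 3), c(4, 5, 3)), spacing = c(2, 2, 3))
  expect_identical(resample_to_reference(v, v), v)

  cst <- volume(array(7, c(4, 4, 4)), spacing = c(2, 2, 2))
  ref <- volume(array(0, c(7, 7, 7)), spacing = c(1.1, 1.1, 1.1))
  expect_equal(range(resample_to_reference(cst, ref)$data), c(7, 7),
               tolerance = 1e-12)

  # 1D ramp upsampled to half-steps: hand linear interpolation
  ramp <- volume(array(c(0, 1, 2), c(3, 1, 1)), spacing = c(1, 1, 1))
  ref1 <- volume(array(0, c(5, 1, 1)), spacing = c(0.5, 1, 1))
  expect_equal(as.vector(resample_to_reference(ramp, ref1)$data),
               c(0, 0.5, 1, 1.5, 2), tolerance = 1e-12)

  far <- volume(array(0, c(3, 3, 3)), origin = c(100, 100, 100))
  expect_error(resample_to_reference(ramp, far), "disjoint")
})
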