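test_that("IABR samples are balanced, disjoint and counted", {
  y <- c(rep(1, 69), rep(0, 49))               # cohort-like imbalance
  cfg <- iabr_control(n_samples = 25, seed = 3)
  ss <- iabr_samples(y, cfg)
  expect_length(ss, 25)
  for (s in ss) {
    expect_length(s$train, 118)
    # class-balanced: counts within 1 of n/2, drawn from own instances
    expect_identical(sum(y[s$train] == 1), 59L)
    expect_identical(sum(y[s$train] == 0), 59L)
    expect_length(intersect(unique(s$train), s$test), 0L)
    expect_gt(length(s$test), 0)
    expect_setequal(unique(y[s$test]), c(0, 1))
  }
  # seeded determinism
  expect_identical(iabr_samples(y, cfg), ss)
  expect_error(iabr_samples(c(1, 0, 0, 0), iabr_control(10)), "at least 2")
})

test_that("ridge-IRLS logistic matches glm and handles separation", {
  set.seed(4)
  X <- matrix(rnorm(900), 300, 3)
  y <- rbinom(300, 1, plogis(drop(X %*% c(1, -0.5, 0.2))))
  f <- logistic_fit(X, y)
  g <- glm(y ~ X, family = binomial)
  expect_equal(unname(f$coef), unname(coef(g)), tolerance = 1e-5)

  # separable single feature: positive slope, saturated probabilities
  ys <- rep(c(0, 1), each = 20)
  Xs <- matrix(ys + 0, ncol = 1)
  fs <- logistic_fit(Xs, ys)
  expect_gt(fs$coef[2], 0)
  p <- mprad:::logistic_predict(fs$coef, Xs)
  expect_true(all(p[ys == 1] > 0.99))
  expect_true(all(p[ys == 0] < 0.01))

  # outcome independent of X: slope near zero
  set.seed(5)
  Xn <- matrix(rnorm(2000), 2000, 1)
  yn <- rep(c(0, 1), 1000)
  expect_lt(abs(logistic_fit(Xn, yn)$coef[2]), 0.1)

  # zero coefficients give probability one half everywhere
  expect_equal(mprad:::logistic_predict(c(0, 0), Xs),
               rep(0.5, nrow(Xs)))
})

test_that("the 0.632+ combination reproduces its formula cases", {
  expect_identical(auc_632plus(0.8, 0.8), 0.8)      # no optimism
  expect_identical(auc_632plus(1.0, 0.5), 0.5)      # maximal overfit
  # R = 0.5 intermediate case
  expect_equal(auc_632plus(0.9, 0.7), 0.9 - 0.2 * (0.632 / 0.816))
  expect_equal(auc_632plus(0.9, 0.7), 0.7451, tolerance = 1e-4)
  # oob below chance is floored at 0.5
  expect_equal(auc_632plus(0.45, 0.40), 0.368 * 0.45 + 0.632 * 0.5)
  # output bounds in the optimistic regime (apparent >= out-of-bag)
  set.seed(6)
  for (i in 1:50) {
    a <- runif(1, 0.5, 1); o <- runif(1, 0, a)
    v <- auc_632plus(a, o)
    expect_gte(v + 1e-12, min(a, max(o, 0.5)))
    expect_lte(v - 1e-12, a)
  }
})

test_that("forward building recovers a planted signal near its Bayes AUC", {
  set.seed(31)
  n <- 300
  d <- c(1.2, 0.8)
  y <- rep(c(1, 0), each = n / 2)
  X <- cbind(rnorm(n, y * d[1]), rnorm(n, y * d[2]), rnorm(n), rnorm(n))
  colnames(X) <- c("s1", "s2", "n1", "n2")
  tab <- data.frame(label = y, X)

  # Bayes-rule AUC oracle on 1e5 fresh draws from the generative model
  nf <- 1e5
  yf <- rep(c(1, 0), each = nf / 2)
  Xf <- cbind(rnorm(nf, yf * d[1]), rnorm(nf, yf * d[2]))
  bayes <- mprad:::roc_auc(drop(Xf %*% d), yf)

  mods <- forward_build_models(c("s1", "s2", "n1", "n2"), tab,
                               iabr_control(n_samples = 100, seed = 7),
                               max_order = 2)
  expect_identical(mods$results[[1]]$features, "s1")
  expect_setequal(mods$results[[2]]$features, c("s1", "s2"))
  expect_equal(mods$results[[2]]$auc632, bayes, tolerance = 0.05)

  # capping beyond the reduced set warns
  expect_warning(forward_build_models(c("s1", "s2"), tab,
                                      iabr_control(10, seed = 1),
                                      max_order = 5), "capping")
})

test_that("monotone relabeling of a model feature leaves the AUC unchanged", {
  set.seed(12)
  y <- rep(c(1, 0), each = 30)
  f <- y + rnorm(60, 0, 0.8)
  t1 <- data.frame(label = y, f = f)
  t2 <- data.frame(label = y, f = exp(2 * f))  # strictly monotone transform
  cfg <- iabr_control(n_samples = 50, seed = 9)
  m1 <- finalize_model("f", t1, cfg)
  m2 <- finalize_model("f", t2, cfg)
  expect_equal(m1$auc632, m2$auc632, tolerance = 1e-10)
})

test_that("order choice follows the plateau rule", {
  perf <- data.frame(order = 1:5, auc632 = c(0.7, 0.8, 0.85, 0.9, 0.95))
  expect_identical(choose_best_order(perf, tol = 0), 5L)   # strictly rising
  perf2 <- data.frame(order = 1:5, auc632 = c(0.7, 0.9, 0.95, 0.9, 0.8))
  expect_identical(choose_best_order(perf2, tol = 0), 3L)  # interior max
  perf3 <- data.frame(order = 1:6,
                      auc632 = c(0.8, 0.9, 0.95, 0.990, 0.991, 0.9905))
  expect_identical(choose_best_order(perf3, tol = 0.005), 4L)  # plateau
  expect_identical(choose_best_order(perf3, tol = 0), 5L)
})

test_that("finalized coefficients average the IABR training fits", {
  set.seed(17)
  y <- rep(c(1, 0), each = 12)
  tab <- data.frame(label = y, f = y + rnorm(24, 0, 0.6))
  cfg <- iabr_control(n_samples = 2, seed = 23)
  fin <- finalize_model("f", tab, cfg)
  # reconstruct the two bootstrap fits by replaying the same seeded stream
  ss <- iabr_samples(y, cfg)
  X <- as.matrix(tab[, "f", drop = FALSE])
  c1 <- logistic_fit(X[ss[[1]]$train, , drop = FALSE], y[ss[[1]]$train])$coef
  c2 <- logistic_fit(X[ss[[2]]$train, , drop = FALSE], y[ss[[2]]$train])$coef
  expect_equal(unname(fin$coefficients), unname((c1 + c2) / 2),
               tolerance = 1e-12)

  # separable feature: slope positive in every bootstrap, hence on average
  ysep <- rep(c(1, 0), each = 10)
  tsep <- data.frame(label = ysep, f = ysep)
  fsep <- finalize_model("f", tsep, iabr_control(n_samples = 20, seed = 2))
  expect_gt(fsep$coefficients["f"], 0)
})

test_that("a fixed finalized model stays at chance under permuted labels", {
  set.seed(40)
  n <- 118
  tab <- data.frame(label = rep(c(1, 0), c(69, 49)),
                    f = rnorm(n), g = rnorm(n))
  inb <- vapply(1:20, function(s) {
    set.seed(3000 + s)
    t2 <- tab; t2$label <- sample(tab$label)
    a <- finalize_model("f", t2, iabr_control(n_samples = 100, seed = s))$auc632
    a >= 0.4 && a <= 0.6
  }, TRUE)
  expect_gte(mean(inb), 0.95)
})

test_that("the top-level radiomic model object behaves like a fitted model", {
  co <- small_cohort()
  ft <- extract_feature_table(co, "std3D")
  m <- radiomic_model(ft, k = 6, max_order = 3,
                      control = iabr_control(n_samples = 30, seed = 5))
  expect_s3_class(m, "radiomic_model")
  expect_identical(nrow(performance_table(m$models)), 3L)
  expect_length(coef(m), length(m$final$features) + 1)
  p <- predict(m, ft)
  expect_true(all(p >= 0 & p <= 1))
  expect_setequal(unique(predict(m, ft, type = "class")), c(0, 1))
  expect_output(print(m), "Radiomic logistic classifier")
  expect_output(print(summary(m)), "Per-order 0.632")
  # strong synthetic separation: near-perfect in-cohort discrimination
  expect_gt(mprad:::roc_auc(p, ft$label), 0.95)
})
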