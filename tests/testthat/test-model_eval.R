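test_that("pointwise log density matches an independent Bernoulli log-pmf", {
  set.seed(3)
  p <- matrix(runif(200, 0.05, 0.95), 8, 25)
  y <- rbinom(25, 1, 0.5)
  ld <- pointwise_log_density(p, y = y)
  oracle <- matrix(NA_real_, 8, 25)
  for (s in 1:8) for (i in 1:25) {
    oracle[s, i] <- dbinom(y[i], 1, p[s, i], log = TRUE)
  }
  expect_equal(ld, oracle, tolerance = 1e-12)
  expect_true(all(ld <= 0))

  # p = 0.5 everywhere: every draw's ELPD is n * ln 0.5, exactly
  n <- 40
  ph <- matrix(0.5, 6, n)
  ld2 <- pointwise_log_density(ph, y = rbinom(n, 1, 0.5))
  expect_identical(unname(rowSums(ld2)), rep(n * log(0.5), 6))

  # perfect predictions approach 0 from below, and boundary p is clamped
  expect_warning(ld3 <- pointwise_log_density(matrix(c(1, 0), 1), y = c(1, 0)))
  expect_true(all(ld3 > -1e-10 & ld3 <= 0))
})

test_that("ELPD totals are additive over any partition of observations", {
  set.seed(4)
  p <- matrix(runif(300, 0.1, 0.9), 10, 30)
  y <- rbinom(30, 1, 0.6)
  ld <- pointwise_log_density(p, y = y)
  parts <- split(1:30, sample(1:4, 30, replace = TRUE))
  total <- rowSums(ld)
  pieces <- Reduce(`+`, lapply(parts, function(ix)
    rowSums(ld[, ix, drop = FALSE])))
  expect_equal(total, pieces, tolerance = 1e-12)
})

test_that("model accuracy: oracle predictor, null predictor, closed-form mean", {
  set.seed(5)
  y <- rbinom(50, 1, 0.5)
  p_oracle <- matrix(y, 20, 50, byrow = TRUE) * 0.98 + 0.01
  acc <- model_accuracy(p_oracle, y = y, rule = "threshold")
  expect_identical(unname(acc$overall), rep(1, 20))

  p_half <- matrix(0.5, 2000, 50)
  acc2 <- model_accuracy(p_half, y = y, rule = "bernoulli")
  expect_equal(mean(acc2$overall), 0.5, tolerance = 0.03)

  # closed form: E[acc per draw] = mean(p y + (1-p)(1-y))
  p <- matrix(runif(4000 * 30, 0.2, 0.8), 4000, 30)
  y3 <- rbinom(30, 1, 0.5)
  acc3 <- model_accuracy(p, y = y3, rule = "bernoulli")
  expected <- mean(colMeans(p) * y3 + (1 - colMeans(p)) * (1 - y3))
  expect_equal(mean(acc3$overall), expected, tolerance = 0.01)

  # counting oracle on a small fixture, threshold rule
  p4 <- matrix(c(0.9, 0.2, 0.6, 0.4), 1)
  y4 <- c(1, 1, 0, 0)
  tp_tn <- sum((p4 > 0.5) == y4)
  expect_equal(unname(model_accuracy(p4, y = y4,
                                     rule = "threshold")$overall),
               tp_tn / 4)
})

test_that("compare_models: self-comparison, antisymmetry, paired oracle", {
  set.seed(6)
  a <- rnorm(500, -300, 5)
  b <- rnorm(500, -320, 5)
  self <- compare_models(a, a)
  expect_identical(self$diff, rep(0, 500))
  ab <- compare_models(a, b)
  ba <- compare_models(b, a)
  expect_equal(ab$diff, -ba$diff, tolerance = 1e-12)
  expect_equal(ab$diff, a - b, tolerance = 1e-12)
  expect_equal(ab$likelihood_ratio, exp(mean(a - b)), tolerance = 1e-9)
  expect_error(compare_models(a, b[-1]), class = "pd_validation_error")
})

test_that("bayesian mean difference: null, dominated, asymptotic oracle", {
  set.seed(7)
  x <- rnorm(100, 0.5, 0.1)
  same <- bayesian_mean_difference(x, x + rnorm(100, 0, 0.1))
  expect_false(same$credible)

  big <- bayesian_mean_difference(rnorm(200, 0.9, 0.05),
                                  rnorm(200, 0.1, 0.05))
  expect_true(big$credible)
  expect_equal(big$mean, 0.8, tolerance = 0.02)

  xa <- rnorm(5000, 0.3, 1)
  xb <- rnorm(5000, 0.1, 1)
  d <- bayesian_mean_difference(xa, xb)
  expect_equal(d$mean, mean(xa) - mean(xb), tolerance = 3 * sqrt(2 / 5000))
  expect_error(bayesian_mean_difference(1, numeric(0)),
               class = "pd_validation_error")
})

test_that("bayesian slope: null, strong signal, OLS oracle", {
  set.seed(8)
  x <- rnorm(200)
  null <- bayesian_slope(x, rnorm(200))
  expect_false(null$credible)
  strong <- bayesian_slope(x, 2 * x + rnorm(200, 0, 0.1))
  expect_true(strong$credible)
  expect_equal(strong$mean, 2, tolerance = 0.05)
  xl <- rnorm(5000)
  yl <- 0.7 * xl + rnorm(5000)
  sl <- bayesian_slope(xl, yl)
  expect_equal(sl$mean, unname(coef(lm(yl ~ xl))[2]), tolerance = 0.01)
  expect_error(bayesian_slope(rep(1, 10), rnorm(10)),
               class = "pd_validation_error")
})

test_that("k-fold: partition property and out-of-sample optimism", {
  cfg <- synth_config(n_participants = 12, seed = 51, model = "two_factor",
                      n_unusable = 0)
  tab <- gen_analysis_table(cfg)
  kf <- suppressWarnings(suppressMessages(
    kfold_evaluate(tab, model_spec("two_factor"), k = 2, seed = 1,
                   chains = 2, iter = 150, warmup = 400)))
  expect_equal(sort(unique(kf$fold)), 1:2)
  expect_length(kf$scored, nrow(tab))        # every trial scored once
  expect_false(anyNA(kf$lpd_out))
  expect_equal(kf$elpd_out, rowSums(kf$lpd_out), tolerance = 1e-12)

  # optimism: in-sample beats out-of-sample in most replicates (scaled
  # down from the 20-replicate property for runtime)
  wins <- vapply(1:4, function(s) {
    t2 <- gen_analysis_table(synth_config(n_participants = 15,
                                          seed = 100 + s,
                                          model = "two_factor",
                                          n_unusable = 0))
    k2 <- suppressWarnings(suppressMessages(
      kfold_evaluate(t2, model_spec("two_factor"), k = 3, seed = s,
                     chains = 2, iter = 150, warmup = 400)))
    mean(k2$elpd_in) > mean(k2$elpd_out)
  }, logical(1))
  expect_gte(mean(wins), 0.75)

  expect_error(kfold_evaluate(tab, model_spec("two_factor"), k = 1),
               class = "pd_config_error")
  expect_error(kfold_evaluate(tab, model_spec("two_factor"),
                              k = nrow(tab) + 1),
               class = "pd_config_error")
})
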