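# Model fits in this file are deliberately small; sampler correctness at
# scale is exercised in test-acceptance.R.

test_that("two_factor fit recovers its generating coefficients", {
  cfg <- synth_config(n_participants = 123, seed = 101,
                      model = "two_factor", n_unusable = 0)
  tab <- gen_analysis_table(cfg)
  fit <- fit_threat_model(tab, model_spec("two_factor"), chains = 2,
                          iter = 600, warmup = 600, seed = 7,
                          rhat_action = "warn")
  truth <- default_truth("two_factor")$beta
  q <- apply(fit$beta, 2, quantile, c(0.025, 0.975))
  for (nm in names(truth)) {
    expect_gte(truth[[nm]], q[1, nm])
    expect_lte(truth[[nm]], q[2, nm])
  }
  # sigma_u in a sane neighborhood of its truth (1.03)
  expect_gt(mean(fit$sigma_u), 0.5)
  expect_lt(mean(fit$sigma_u), 1.8)
  expect_true(all(fit$sigma_u > 0))
  expect_true(all(is.finite(fit$diagnostics$rhat)))
})

test_that("large-n posterior agrees with an adaptive-quadrature ML oracle", {
  skip_if_not_installed("lme4")
  set.seed(42)
  J <- 150; nper <- 20; n <- J * nper
  pid <- rep(sprintf("P%03d", 1:J), each = nper)
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.5)
  u <- rep(rnorm(J, 0, 0.8), each = nper)
  y <- rbinom(n, 1, plogis(0.5 + 0.9 * x1 - 0.7 * x2 + u))
  X <- cbind("(Intercept)" = 1, x1 = x1, x2 = x2)
  fit <- fit_model(X, y, pid,
                   model_spec("custom", predictors = c("x1", "x2"),
                              max_interaction_order = 1),
                   chains = 2, iter = 600, warmup = 600, seed = 5,
                   rhat_action = "warn")
  g <- lme4::glmer(y ~ x1 + x2 + (1 | pid), family = binomial, nAGQ = 10)
  bayes <- colMeans(fit$beta)
  ml <- unname(lme4::fixef(g))
  # prior shrinkage and mean-vs-mode asymmetry leave small gaps at this n;
  # 0.05 is ~1/4 of the posterior SD here
  expect_equal(unname(bayes), ml, tolerance = 0.05)
  expect_equal(mean(fit$sigma_u),
               sqrt(unname(unlist(lme4::VarCorr(g)))), tolerance = 0.1)
})

test_that("with no data the posterior reproduces the prior", {
  spec <- model_spec("two_factor")
  X <- matrix(numeric(0), nrow = 0, ncol = 1,
              dimnames = list(NULL, "(Intercept)"))
  fit <- fit_model(X, integer(0), character(0), spec, chains = 4,
                   iter = 1000, warmup = 800, seed = 31,
                   rhat_action = "warn")
  draws <- fit$beta[, 1]
  # intercept prior: Student-t(3, 0, 10)
  ks <- suppressWarnings(stats::ks.test(draws, function(q) stats::pt(q / 10, df = 3)))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("participant relabeling leaves fixed-effect posteriors unchanged", {
  cfg <- synth_config(n_participants = 40, seed = 17, model = "two_factor",
                      n_unusable = 0)
  tab <- gen_analysis_table(cfg)
  spec <- model_spec("two_factor")
  f1 <- fit_threat_model(tab, spec, chains = 2, iter = 600, warmup = 600,
                         seed = 1, rhat_action = "warn")
  perm <- setNames(sample(unique(tab$participant_id)),
                   unique(tab$participant_id))
  tab2 <- tab
  tab2$participant_id <- unname(perm[tab$participant_id])
  f2 <- fit_threat_model(tab2, spec, chains = 2, iter = 600, warmup = 600,
                         seed = 2, rhat_action = "warn")
  mcse <- apply(f1$beta, 2, sd) / sqrt(pmin(
    f1$diagnostics$ess[seq_len(ncol(f1$beta))], nrow(f1$beta)))
  gap <- abs(colMeans(f1$beta) - colMeans(f2$beta))
  expect_true(all(gap < 6 * mcse + 0.02))
})

test_that("posterior_predict handles seen, unseen and omitted participants", {
  cfg <- synth_config(n_participants = 20, seed = 23, model = "two_factor",
                      n_unusable = 0)
  tab <- gen_analysis_table(cfg)
  fit <- fit_threat_model(tab, model_spec("two_factor"), chains = 2,
                          iter = 300, warmup = 500, seed = 3,
                          rhat_action = "warn")
  p <- posterior_predict(fit)
  expect_identical(dim(p), c(600L, nrow(fit$data$X)))
  expect_true(all(p > 0 & p < 1))
  # population-level row of zeros except intercept: inverse-logit(intercept)
  x0 <- matrix(c(1, 0, 0, 0), 1)
  p0 <- posterior_predict(fit, X = x0, participant = NA)
  expect_equal(as.vector(p0), unname(plogis(fit$beta[, 1])),
               tolerance = 1e-12)
  # unseen participant: marginalized draws differ from population-level
  pu <- posterior_predict(fit, X = x0, participant = "NEW")
  expect_gt(sd(pu - p0), 0)
  expect_error(posterior_predict(fit, X = matrix(1, 1, 3)),
               class = "pd_validation_error")
})

test_that("condition means equal brute-force averaging of posterior_predict", {
  cfg <- synth_config(n_participants = 20, seed = 29, model = "two_factor",
                      n_unusable = 0)
  tab <- gen_analysis_table(cfg)
  fit <- fit_threat_model(tab, model_spec("two_factor"), chains = 2,
                          iter = 300, warmup = 500, seed = 5,
                          rhat_action = "warn")
  set.seed(77)
  cm <- condition_means(fit, site_type = "spoof", auth_level = "EV")
  keep <- fit$table_info$site_type == "spoof" &
    fit$table_info$auth_level == "EV"
  set.seed(77)
  p <- posterior_predict(fit, X = fit$data$X[keep, , drop = FALSE],
                         participant = NULL)
  expect_equal(cm$draws, rowMeans(p), tolerance = 1e-12)
  expect_true(all(cm$draws > 0 & cm$draws < 1))

  # perfect-separation toy check: all non-spoof correct
  tab2 <- tab
  tab2$accuracy[tab2$site_type == "non_spoof"] <- 1L
  fit2 <- fit_threat_model(tab2, model_spec("two_factor"), chains = 2,
                           iter = 300, warmup = 500, seed = 9,
                           rhat_action = "none")
  cm2 <- condition_means(fit2, site_type = "non_spoof")
  expect_gt(cm2$mean, 0.95)
  # spoof minus non-spoof difference machinery from the same draws
  d <- condition_means(fit, site_type = "non_spoof")$draws -
    condition_means(fit, site_type = "spoof")$draws
  expect_length(d, nrow(fit$beta))
})

test_that("fit_model validates inputs and fails loudly on non-convergence", {
  X <- cbind("(Intercept)" = rep(1, 10), x = rnorm(10))
  expect_error(fit_model(X, rep(2, 10), rep(c("a", "b"), 5)),
               class = "pd_validation_error")
  expect_error(fit_model(X, rbinom(10, 1, 0.5), rep("a", 10)),
               class = "pd_validation_error")
  # absurdly short chains cannot converge -> loud diagnostic error
  set.seed(1)
  Xb <- cbind("(Intercept)" = 1, x = rnorm(200))
  yb <- rbinom(200, 1, 0.5)
  pid <- rep(sprintf("p%d", 1:20), each = 10)
  expect_error(
    suppressWarnings(fit_model(Xb, yb, pid, chains = 4, iter = 12,
                               warmup = 5, seed = 2)),
    class = "pd_convergence_error")
})
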