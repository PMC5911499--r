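## Posterior fitting and prediction for the hierarchical logistic models.
## Sampling is done by an adaptive Hamiltonian Monte Carlo sampler (src/)
## on the non-centered parameterization; diagnostics are split-Rhat and an
## autocorrelation-based effective sample size.

#' Split-chain R-hat
#'
#' Gelman-Rubin potential scale reduction computed after splitting each
#' chain in half, the standard convergence diagnostic for MCMC output.
#'
#' @param draws matrix of draws, iterations x chains.
#' @return scalar R-hat (1 = perfect mixing).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- n %/% 2
  if (half < 2) return(NA_real_)
  sub <- cbind(draws[1:half, , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Effective sample size
#'
#' Autocorrelation-based bulk effective sample size using Geyer's initial
#' positive sequence, pooled over chains.
#'
#' @param draws matrix of draws, iterations x chains.
#' @return estimated effective sample size.
#' @export
ess_basic <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  m <- ncol(draws)
  if (n < 4) return(NA_real_)
  ac <- sapply(seq_len(m), function(c) {
    a <- acf(draws[, c], lag.max = min(n - 2, 500), plot = FALSE,
             demean = TRUE)
    as.vector(a$acf)
  })
  ac <- matrix(ac, ncol = m)
  chain_var <- apply(draws, 2, var)
  W <- mean(chain_var)
  varplus <- W * (n - 1) / n + var(colMeans(draws))
  if (varplus <= 0) return(n * m)
  # combined autocorrelation at each lag
  rho <- 1 - (W - colMeans(t(ac) * chain_var))[-1] / varplus
  # Geyer initial positive sequence on paired sums
  npair <- length(rho) %/% 2
  tau <- 1
  if (npair > 0) {
    p <- rho[seq_len(2 * npair)]
    psum <- p[seq(1, 2 * npair, 2)] + p[seq(2, 2 * npair, 2)]
    k <- which(psum <= 0)
    if (length(k)) psum <- psum[seq_len(k[1] - 1)]
    tau <- 1 + 2 * sum(pmax(psum, 0))
  }
  max(1, n * m / max(tau, 1e-8))
}

#' Fit a hierarchical Bayesian logistic regression
#'
#' Samples the posterior of `logit P(y = 1) = X beta + u[participant]`,
#' with `u_j ~ Normal(0, sigma_u)` partially pooled participant intercepts,
#' Student-t(3) priors on the coefficients (scale 5; intercept scale 10)
#' and a half-Student-t(3, 0, 10) prior on `sigma_u`, via adaptive
#' Hamiltonian Monte Carlo. The fit fails loudly (or warns, per
#' `rhat_action`) if any parameter's split R-hat exceeds `rhat_max`.
#'
#' @param design design list from [build_design_matrix()], or a bare
#'   numeric matrix whose first column is the intercept.
#' @param y binary outcome vector (0/1), one per design row.
#' @param participant participant id per design row (factor or character).
#' @param spec the [model_spec()] (supplies the priors).
#' @param chains,iter,warmup sampler layout; `iter` counts post-warmup
#'   draws per chain.
#' @param seed RNG seed for reproducible sampling.
#' @param target_accept dual-averaging acceptance target.
#' @param rhat_max convergence threshold (default 1.01).
#' @param rhat_action `"error"`, `"warn"` or `"none"` when `rhat_max` is
#'   exceeded.
#' @param max_leapfrog,int_time HMC trajectory controls.
#' @return object of class `pd_fit`: posterior draw matrices `beta`
#'   (draws x coefficients), `u` (draws x participants), vector `sigma_u`,
#'   a `diagnostics` data frame (R-hat, ESS per parameter), the data and
#'   metadata needed for prediction.
#' @export
fit_model <- function(design, y, participant, spec = model_spec("custom",
                        predictors = "x", max_interaction_order = 1),
                      chains = 4, iter = 1000, warmup = 1000, seed = NULL,
                      target_accept = 0.8, rhat_max = 1.01,
                      rhat_action = c("error", "warn", "none"),
                      max_leapfrog = 64, int_time = 2.5) {
  rhat_action <- match.arg(rhat_action)
  X <- if (is.list(design) && !is.null(design$X)) design$X else as.matrix(design)
  transform <- if (is.list(design)) design$transform else NULL
  y <- as.integer(y)
  n <- nrow(X)
  if (length(y) != n) pd_stop("pd_validation_error", "length(y) != nrow(X)")
  if (n > 0 && !all(y %in% 0:1)) {
    pd_stop("pd_validation_error", "outcomes must be binary 0/1")
  }
  labels <- colnames(X) %||% paste0("b", seq_len(ncol(X)))
  if (n > 0) {
    participant <- as.character(participant)
    if (length(participant) != n) {
      pd_stop("pd_validation_error", "length(participant) != nrow(X)")
    }
    levels_u <- sort(unique(participant))
    if (length(levels_u) < 2) {
      pd_stop("pd_validation_error", "need >= 2 participants")
    }
    g <- match(participant, levels_u) - 1L
  } else {
    levels_u <- character(0)
    g <- integer(0)
  }
  pr <- spec$priors
  prior_scale <- rep(pr$coef_scale, ncol(X))
  prior_scale[labels == "(Intercept)"] <- pr$intercept_scale

  if (!is.null(seed)) set.seed(seed)
  res <- .hmc_fit_cpp(X, y, g, length(levels_u), prior_scale, pr$df,
                      pr$sigma_scale, pr$sigma_df, as.integer(chains),
                      as.integer(warmup), as.integer(iter), target_accept,
                      0.1, as.integer(max_leapfrog), int_time)
  p <- ncol(X); J <- length(levels_u); dim <- p + J + 1
  # draws: list of iter x dim chain matrices
  all_draws <- do.call(rbind, res$draws)
  beta <- all_draws[, seq_len(p), drop = FALSE]
  colnames(beta) <- labels
  u_raw <- if (J > 0) all_draws[, p + seq_len(J), drop = FALSE] else
    matrix(0, nrow(all_draws), 0)
  sigma_u <- exp(all_draws[, dim])
  u <- u_raw * sigma_u
  colnames(u) <- levels_u

  par_names <- c(labels, if (J > 0) paste0("u[", levels_u, "]"), "sigma_u")
  diag_df <- data.frame(parameter = par_names,
                        rhat = NA_real_, ess = NA_real_,
                        stringsAsFactors = FALSE)
  for (k in seq_len(dim)) {
    mat <- sapply(res$draws, function(d) d[, k])
    if (k == dim) mat <- exp(mat)
    diag_df$rhat[k] <- split_rhat(mat)
    diag_df$ess[k] <- ess_basic(mat)
  }
  bad <- diag_df$parameter[is.finite(diag_df$rhat) &
                             diag_df$rhat > rhat_max]
  if (length(bad)) {
    msg <- sprintf("R-hat > %.3f for: %s", rhat_max,
                   paste(head(bad, 8), collapse = ", "))
    if (rhat_action == "error") pd_stop("pd_convergence_error", "%s", msg)
    if (rhat_action == "warn") warning(msg)
  }
  structure(list(beta = beta, u = u, sigma_u = sigma_u,
                 labels = labels, participants = levels_u,
                 transform = transform, spec = spec,
                 chains = chains, iter = iter, warmup = warmup,
                 eps = res$eps, accept_rate = res$accept_rate,
                 divergences = res$divergences,
                 diagnostics = diag_df,
                 data = list(X = X, y = y,
                             participant = if (n > 0) participant else
                               character(0))),
            class = "pd_fit")
}

#' @export
print.pd_fit <- function(x, ...) {
  cat(sprintf(
    "<pd_fit %s: %d obs, %d participants, %d draws (%d chains)>\n",
    x$spec$name, length(x$data$y), length(x$participants),
    nrow(x$beta), x$chains))
  cat(sprintf("  max R-hat %.3f, min ESS %.0f, sigma_u mean %.2f\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE), mean(x$sigma_u)))
  invisible(x)
}

#' Fit an accuracy model directly from an analysis table
#'
#' Convenience wrapper: builds the design matrix for `spec` from the
#' analysis table (recording the transform), fits the model, and stores the
#' condition columns so that [condition_means()] can be used on the result.
#'
#' @param table analysis table with measure columns filled.
#' @param spec a [model_spec()].
#' @param ... passed to [fit_model()].
#' @return a `pd_fit` with `$table_info` attached.
#' @export
fit_threat_model <- function(table, spec, ...) {
  d <- build_design_matrix(table, spec)
  tab <- table[d$rows, , drop = FALSE]
  fit <- fit_model(d, y = tab$accuracy, participant = tab$participant_id,
                   spec = spec, ...)
  fit$table_info <- data.frame(site_type = tab$site_type,
                               auth_level = tab$auth_level,
                               stringsAsFactors = FALSE)
  fit
}

#' Posterior predictive success probabilities
#'
#' Inverse-logit of the per-draw linear predictor for each supplied design
#' row. For participants seen during fitting their posterior intercept
#' draws are used; for unseen (or `NULL`) participants a fresh intercept is
#' drawn from `Normal(0, sigma_u)` independently per posterior draw,
#' marginalizing the participant effect.
#'
#' @param fit a `pd_fit`.
#' @param X design rows on the fit's scale (project new data with the fit's
#'   `transform` via [build_design_matrix()]); defaults to the training
#'   design.
#' @param participant participant ids per row; `NULL` marginalizes the
#'   participant effect (fresh draw per draw and row); `NA` omits it
#'   entirely (population-level linear predictor only).
#' @return matrix draws x rows of probabilities in (0, 1).
#' @export
posterior_predict <- function(fit, X = NULL, participant = NULL) {
  used_default <- is.null(X)
  X <- if (used_default) fit$data$X else as.matrix(X)
  if (used_default && is.null(participant)) participant <- fit$data$participant
  no_u <- length(participant) == 1 && is.na(participant[1])
  if (ncol(X) != ncol(fit$beta)) {
    pd_stop("pd_validation_error",
            "design has %d columns; fit expects %d", ncol(X), ncol(fit$beta))
  }
  S <- nrow(fit$beta)
  eta <- fit$beta %*% t(X)  # S x n
  n <- ncol(eta)
  if (no_u) {
    # population-level only
  } else if (is.null(participant)) {
    ueff <- matrix(rnorm(S * n), S, n) * fit$sigma_u
    eta <- eta + ueff
  } else {
    participant <- as.character(participant)
    idx <- match(participant, fit$participants)
    for (i in seq_len(n)) {
      if (is.na(idx[i])) {
        eta[, i] <- eta[, i] + rnorm(S) * fit$sigma_u
      } else {
        eta[, i] <- eta[, i] + fit$u[, idx[i]]
      }
    }
  }
  plogis(eta)
}

#' Posterior distribution of condition-cell accuracy
#'
#' Per-draw average of posterior predictive probabilities over all fitted
#' design rows in one site-type x authentication cell, with participant
#' effects marginalized (fresh `Normal(0, sigma_u)` intercepts per draw).
#' This is the machinery behind condition-mean and condition-difference
#' summaries such as "predicted accuracy in the non-spoof condition".
#'
#' @param fit a `pd_fit` from [fit_threat_model()].
#' @param site_type `"non_spoof"`, `"spoof"`, or `NULL` for all.
#' @param auth_level `"PE"`, `"SV"`, `"EV"`, or `NULL` for all.
#' @return list with the per-draw `draws`, their `mean` and 95% `ui`.
#' @export
condition_means <- function(fit, site_type = NULL, auth_level = NULL) {
  if (is.null(fit$table_info)) {
    pd_stop("pd_validation_error",
            "fit lacks condition info; use fit_threat_model()")
  }
  keep <- rep(TRUE, nrow(fit$table_info))
  if (!is.null(site_type)) keep <- keep & fit$table_info$site_type == site_type
  if (!is.null(auth_level)) keep <- keep & fit$table_info$auth_level == auth_level
  if (!any(keep)) pd_stop("pd_validation_error", "no rows in that condition")
  p <- posterior_predict(fit, X = fit$data$X[keep, , drop = FALSE],
                         participant = NULL)
  draws <- rowMeans(p)
  list(draws = draws, mean = mean(draws),
       ui = unname(quantile(draws, c(0.025, 0.975))))
}
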