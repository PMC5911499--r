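## Synthetic study generator. The generator targets the *measures*, not the
## physiology: covariates (AUC / SE / RT on their transformed modeling
## scales, knowledge, familiarity) are drawn first from population
## distributions matching the study's descriptive statistics, outcomes are
## then generated from the hierarchical logistic structure conditional on
## them, and trajectories are synthesized backwards so that the kinematics
## and entropy stages recover the intended measure values.

# population targets on the transformed modeling scales
pd_pop_targets <- list(
  knowledge = c(mean = 0.52, sd = 0.25),
  familiarity = c(mean = 3.17, sd = 1.60),
  auc_t = c(mean = 1.31, sd = 1.29),     # signed-log scale
  se_log = c(mean = -2.34, sd = 0.65),   # log scale
  rt_ln = c(mean = 8.96, sd = 0.51))     # log milliseconds

# transform metadata putting natural-scale columns onto the standardized
# population scale (used when generating outcomes, so the true coefficients
# live on the same scale the fitted models use). Continuous targets use the
# same 2-SD design unit as build_design_matrix().
pd_target_transform <- function(preds, scale_sd = 2) {
  tgt <- function(nm) list(center = pd_pop_targets[[nm]][["mean"]],
                           scale = scale_sd * pd_pop_targets[[nm]][["sd"]])
  tf <- list(
    spoof = list(center = 0, scale = 1),
    auth = list(center = 0, scale = 1),
    knowledge = tgt("knowledge"),
    familiarity = tgt("familiarity"),
    auc = tgt("auc_t"),
    se = tgt("se_log"),
    rt = tgt("rt_ln"))
  tf[preds]
}

#' Generating truths for the simulation studies
#'
#' Named coefficient vectors (on the standardized design scale) and
#' between-participant intercept SDs used as simulation ground truth; the
#' point estimates of the credible coefficients of the fitted accuracy
#' models, with all other design coefficients 0.
#'
#' @param name `"two_factor"`, `"survey_based"` or `"real_time"`.
#' @return list with `beta` (named vector) and `sigma_u`.
#' @export
default_truth <- function(name = c("two_factor", "survey_based",
                                   "real_time")) {
  name <- match.arg(name)
  switch(name,
    two_factor = list(
      beta = c("(Intercept)" = 1.63, "spoof" = -1.69,
               "spoof:auth" = -0.56),
      sigma_u = 1.03),
    survey_based = list(
      beta = c("(Intercept)" = 1.88, "spoof" = -1.93, "knowledge" = 1.15,
               "familiarity" = 1.15, "spoof:auth" = -0.83,
               "auth:familiarity" = 1.09),
      sigma_u = 0.88),
    real_time = list(
      beta = c("(Intercept)" = 2.18, "spoof" = -2.43, "auth" = 0.74,
               "knowledge" = 2.12, "familiarity" = 1.10, "auc" = 1.57,
               "se" = -1.47, "spoof:auth" = -1.40, "spoof:auc" = -3.90,
               "spoof:se" = 2.01, "spoof:rt" = 1.66, "auth:auc" = 1.73,
               "knowledge:se" = 2.35, "auc:se" = 1.60, "se:rt" = -2.69,
               "spoof:auth:auc" = -2.26, "spoof:auc:se" = -3.25,
               "auth:knowledge:auc" = 1.82, "auth:knowledge:se" = -1.54,
               "auc:se:rt" = 1.98),
      sigma_u = 0.85))
}

#' Configuration of a synthetic study
#'
#' Defaults reproduce the stated study world: 123 participants, the
#' counterbalanced 2 (site type) x 3 (authentication) within-participant
#' design (6 trials each), covariate populations matching the descriptive
#' statistics (knowledge mean 0.52 / SD 0.25; familiarity mean 3.17 /
#' SD 1.60; AUC, SE and RT normal on their transformed scales), outcomes
#' from the hierarchical logistic structure with the `real_time` truth
#' coefficients and participant-intercept SD 0.85, 60 Hz trajectory
#' sampling, and 2 trials flagged unusable (mirroring the undocumented
#' drop from 738 to 736 analysis rows). Incorrect-response time penalties
#' (10 s for logging into a spoof site, 20 s for backing out of a
#' legitimate one) are recorded as metadata; they do not enter the models.
#'
#' @param n_participants number of participants.
#' @param trials_per_participant must be a multiple of 6 (the design is
#'   replicated `r` times for power studies).
#' @param seed RNG seed; seeds fully determine the generated study.
#' @param model truth model name, see [default_truth()].
#' @param beta,sigma_u override the generating truth.
#' @param rate trajectory sampling rate in Hz.
#' @param n_unusable number of randomly flagged unusable trials.
#' @param screen screen size in pixels.
#' @param penalties_s named penalties metadata.
#' @return object of class `pd_synth_config`.
#' @export
synth_config <- function(n_participants = 123, trials_per_participant = 6,
                         seed = 1, model = "real_time", beta = NULL,
                         sigma_u = NULL, rate = 60, n_unusable = 2,
                         screen = c(1920, 1080),
                         penalties_s = c(login_spoof = 10, back_legit = 20)) {
  if (trials_per_participant %% 6 != 0) {
    pd_stop("pd_config_error",
            "trials_per_participant must be a multiple of 6")
  }
  truth <- default_truth(model)
  structure(list(n_participants = as.integer(n_participants),
                 trials_per_participant = as.integer(trials_per_participant),
                 seed = as.integer(seed), model = model,
                 beta = beta %||% truth$beta,
                 sigma_u = sigma_u %||% truth$sigma_u,
                 rate = rate, n_unusable = as.integer(n_unusable),
                 screen = screen, penalties_s = penalties_s),
            class = "pd_synth_config")
}

#' Generate the counterbalanced trial design
#'
#' Every participant receives all six site-type x authentication cells in
#' independently randomized order; website-version sets alternate between
#' the two counterbalancing halves of the sample.
#'
#' @param config a [synth_config()].
#' @return data frame with one row per trial: `participant_id`, `trial_id`,
#'   `site_type`, `auth_level`, `version`.
#' @export
gen_design <- function(config = synth_config()) {
  set.seed(config$seed)
  cells <- expand.grid(site_type = pd_site_types,
                       auth_level = pd_auth_levels,
                       stringsAsFactors = FALSE)
  reps <- config$trials_per_participant / 6
  out <- lapply(seq_len(config$n_participants), function(i) {
    ord <- sample(rep(seq_len(6), reps))
    data.frame(participant_id = sprintf("P%03d", i),
               trial_id = sprintf("T%d", seq_along(ord)),
               site_type = cells$site_type[ord],
               auth_level = cells$auth_level[ord],
               version = if (i %% 2 == 1) "A" else "B",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# familiarity category probabilities achieving the target mean/sd: mixture
# of a uniform over 1..5 and extra mass on the endpoints
familiarity_probs <- function(mu = 3.17, sd = 1.60) {
  ex2 <- sd^2 + mu^2
  # solve -10*l + 24*l*w = ex2 - 11 ;  l*(4w - 2) = mu - 3
  lambda <- ((ex2 - 11) - 6 * (mu - 3)) / 2
  w <- ((mu - 3) + 2 * lambda) / (4 * lambda)
  p <- rep((1 - lambda) / 5, 5)
  p[1] <- p[1] + lambda * (1 - w)
  p[5] <- p[5] + lambda * w
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    pd_stop("pd_config_error", "infeasible familiarity mean/sd targets")
  }
  p
}

# draw per-trial covariates on their natural scales
gen_covariates <- function(design, config) {
  pids <- unique(design$participant_id)
  npart <- length(pids)
  # knowledge: participant-level; Beta success probability plus 10-item
  # binomial noise calibrated so the total SD matches the target
  kt <- pd_pop_targets$knowledge
  m <- kt[["mean"]]
  v_total <- kt[["sd"]]^2
  # var(k) = var(p) + E[p(1-p)]/10 with E[p(1-p)] = m - var(p) - m^2
  v_p <- (v_total - (m - m^2) / 10) / (1 - 1 / 10)
  kappa <- m * (1 - m) / v_p - 1
  p_i <- rbeta(npart, m * kappa, (1 - m) * kappa)
  knowledge_correct <- rbinom(npart, 10, p_i)
  names(knowledge_correct) <- pids

  ft <- pd_pop_targets$familiarity
  fp <- familiarity_probs(ft[["mean"]], ft[["sd"]])
  cells <- site_label(rep(pd_site_types, each = 3),
                      rep(pd_auth_levels, times = 2))
  fam <- matrix(sample(1:5, npart * 6, replace = TRUE, prob = fp),
                nrow = npart, dimnames = list(pids, cells))

  n <- nrow(design)
  at <- pd_pop_targets$auc_t
  st <- pd_pop_targets$se_log
  rt <- pd_pop_targets$rt_ln
  auc_t <- rnorm(n, at[["mean"]], at[["sd"]])
  se_log <- rnorm(n, st[["mean"]], st[["sd"]])
  rt_ln <- rnorm(n, rt[["mean"]], rt[["sd"]])
  data.frame(
    knowledge = knowledge_correct[design$participant_id] / 10,
    knowledge_correct = knowledge_correct[design$participant_id],
    familiarity = fam[cbind(design$participant_id,
                            site_label(design$site_type,
                                       design$auth_level))],
    auc = inv_signed_log(auc_t),
    se_raw = exp(se_log), se_log = se_log,
    rt_s = exp(rt_ln) / 1000,
    stringsAsFactors = FALSE)
}

#' Generate outcomes from the hierarchical logistic structure
#'
#' Draws participant intercepts `u_j ~ Normal(0, sigma_u)`, forms
#' `P(correct) = inverse-logit(X beta + u_j)` where `X` is the
#' full-factorial standardized design implied by the predictors named in
#' `beta` (standardization uses the fixed population targets, so `beta`
#' lives on the same scale the fitted models estimate), and samples
#' accuracy. The response follows from accuracy and site type (a correct
#' non-spoof trial is a `login`, a correct spoof trial a `back`).
#'
#' @param design trial design from [gen_design()].
#' @param covariates per-trial natural-scale covariates (columns
#'   `knowledge`, `familiarity`, `auc`, `se_raw`/`se_log`, `rt_s` as
#'   needed).
#' @param beta named true coefficient vector (design labels).
#' @param sigma_u participant intercept SD (>= 0).
#' @param spec optional [model_spec()]; defaults to the smallest standard
#'   spec containing all predictors named in `beta`.
#' @return `design` with added `accuracy`, `response`, `u`, `p_true`.
#' @export
gen_outcomes <- function(design, covariates, beta, sigma_u, spec = NULL) {
  tab <- cbind(design, covariates)
  if (is.null(spec)) {
    preds <- unique(unlist(strsplit(setdiff(names(beta), "(Intercept)"),
                                    ":", fixed = TRUE)))
    std <- c("two_factor", "survey_based", "real_time")
    for (nm in std) {
      if (all(preds %in% model_spec(nm)$predictors)) { spec <- model_spec(nm); break }
    }
    if (is.null(spec)) {
      pd_stop("pd_config_error", "no standard spec covers predictors: %s",
              paste(preds, collapse = ", "))
    }
  }
  d <- build_design_matrix(tab, spec,
                           transform = pd_target_transform(spec$predictors),
                           na_action = "error")
  miss <- setdiff(names(beta), d$labels)
  if (length(miss)) {
    pd_stop("pd_config_error", "truth names not in design: %s",
            paste(miss, collapse = ", "))
  }
  bfull <- setNames(numeric(length(d$labels)), d$labels)
  bfull[names(beta)] <- beta
  pids <- unique(design$participant_id)
  u <- setNames(rnorm(length(pids), 0, sigma_u), pids)
  eta <- as.vector(d$X %*% bfull) + u[design$participant_id]
  p <- plogis(eta)
  acc <- rbinom(length(p), 1, p)
  design$accuracy <- acc
  design$response <- ifelse(design$site_type == "non_spoof",
                            ifelse(acc == 1, "login", "back"),
                            ifelse(acc == 1, "back", "login"))
  design$u <- unname(u[design$participant_id])
  design$p_true <- p
  design
}

#' Generate a complete synthetic analysis table (no trajectories)
#'
#' Runs design, covariate and outcome generation and assembles the
#' analysis-table layout directly, bypassing trajectory synthesis and
#' measurement. This is the fast path for model-level simulation studies
#' (parameter recovery, cross-validated comparison); [gen_dataset()] is the
#' full-pipeline path.
#'
#' @param config a [synth_config()].
#' @return analysis table with measure columns filled from the generating
#'   values, plus `u` and `p_true` truth columns.
#' @export
gen_analysis_table <- function(config = synth_config()) {
  design <- gen_design(config)  # seeds the stream
  cov <- gen_covariates(design, config)
  out <- gen_outcomes(design, cov, config$beta, config$sigma_u)
  unusable <- rep(FALSE, nrow(design))
  if (config$n_unusable > 0) {
    unusable[sample(nrow(design), config$n_unusable)] <- TRUE
  }
  data.frame(
    participant_id = out$participant_id, trial_id = out$trial_id,
    site_type = out$site_type, auth_level = out$auth_level,
    response = out$response, accuracy = out$accuracy,
    usable = !unusable,
    knowledge = cov$knowledge,
    indicator_score = NA_real_,
    familiarity = cov$familiarity,
    auc = cov$auc, se_raw = cov$se_raw, se_log = cov$se_log,
    rt_s = cov$rt_s,
    u = out$u, p_true = out$p_true,
    stringsAsFactors = FALSE)
}

# run expr under its own RNG stream, restoring the caller's stream after
with_isolated_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Empirical map from perpendicular AR(1) jitter amplitude (chord units) to
# measured multiscale sample entropy of the distance-to-endpoint series.
# The attainable entropy depends on the arc height as well (large loops
# have an irreducible geometric SampEn floor), so the map is built per
# arc-area bucket; memoized per sampling rate.
jitter_amp_for_se <- function(target_se, area, rate,
                              n_ref = max(60, round(6 * rate))) {
  key <- sprintf("jitmap_%g_%d", rate, n_ref)
  map <- .pd_cache[[key]]
  if (is.null(map)) {
    amps <- c(0.004, 0.015, 0.06, 0.25, 0.8)
    areas <- c(0.5, 3, 12)
    chord_ref <- 550  # typical start-to-button distance in pixels
    cfg <- entropy_config()
    map <- with_isolated_rng(20181604, {
      se <- sapply(areas, function(ar) {
        vapply(amps, function(a) {
          vals <- vapply(1:3, function(rep) {
            pth <- synth_path_math(n_ref, area = ar, amp = a, phi = 0.9,
                                   angle = pi / 4)
            # probe through the integer-pixel quantization the written
            # trajectories will undergo
            x <- round(pth$x * chord_ref) / chord_ref
            y <- round(pth$y * chord_ref) / chord_ref
            d <- sqrt((x - x[n_ref])^2 + (y - y[n_ref])^2)
            res <- tryCatch(multiscale_sample_entropy(d, cfg),
                            pd_entropy_error = function(e) NULL)
            if (is.null(res)) NA_real_ else res$se_raw
          }, numeric(1))
          mean(vals, na.rm = TRUE)
        }, numeric(1))
      })
      list(amps = amps, areas = areas, se = se)  # se: amps x areas
    })
    .pd_cache[[key]] <- map
  }
  bucket <- which.min(abs(log(pmax(abs(area), 0.1)) - log(map$areas)))
  se_curve <- map$se[, bucket]
  ok <- is.finite(se_curve) & se_curve > 0
  if (sum(ok) < 2) return(map$amps[1])
  # enforce a monotone curve for inversion, then interpolate on log scales
  se_mono <- cummax(se_curve[ok]) * (1 + 1e-9 * seq_len(sum(ok)))
  la <- stats::approx(log(se_mono), log(map$amps[ok]),
                      xout = log(target_se), rule = 2, ties = "ordered")$y
  exp(la)
}

# Quadratic arc plus AR(1) perpendicular jitter in the canonical math
# frame. Positive offsets point toward the non-chosen alternative
# (`alt_side` is +1 for login, whose alternative lies left of the chord,
# -1 for back). Two features make the distance-to-endpoint series behave
# like recorded mouse data rather than a sterile ramp: mildly variable
# progression speed, and a terminal dwell hovering at the click position
# (recurrences near zero distance keep SampEn defined and low for smooth
# paths). Jitter amplitude rides on the arc scale so relative
# irregularity - what SD-scaled entropy radii see - is comparable across
# arc heights.
synth_path_math <- function(n, area, amp, phi, angle, alt_side = 1,
                            dwell_frac = 0.15, speed_noise = 0.08) {
  n2 <- max(4L, round(dwell_frac * n))
  n1 <- n - n2
  sp <- pmax(0, 1 + as.vector(stats::filter(rnorm(n1 - 1, 0, speed_noise),
                                            0.95, method = "recursive")))
  if (max(sp) <= 0) sp <- rep(1, n1 - 1)
  s <- c(0, cumsum(sp))  # progression starts exactly on the chord origin
  s <- c(s / max(s), rep(1, n2))
  scale <- sqrt(1 + (1.5 * area)^2)
  innov <- rnorm(n, 0, amp * scale * sqrt(1 - phi^2))
  j <- as.vector(stats::filter(innov, phi, method = "recursive"))
  env <- c(sin(pi * s[seq_len(n1)]) + 0.15, rep(0.15, n2))
  env[n] <- 0  # the click itself is exact
  # solve for the apex height h such that the *discretized* signed area
  # toward the alternative equals `area` exactly, accounting for the area
  # the jitter realization happens to enclose
  trapz <- function(f) sum(0.5 * (f[-1] + f[-n]) * diff(s))
  arc <- 4 * s * (1 - s)
  a_jit <- trapz(j * env)
  h <- (area - alt_side * a_jit) / trapz(arc)
  offset <- alt_side * h * arc + j * env
  ex <- cos(angle); ey <- sin(angle)
  # left normal of the chord direction
  nx <- -ey; ny <- ex
  list(x = s * ex + offset * nx, y = s * ey + offset * ny)
}

#' Synthesize one raw trajectory with target measure values
#'
#' Builds a quadratic arc from a start position to the response button with
#' its perpendicular apex calibrated so the normalized signed AUC hits
#' `target_auc` (arc area over a unit chord is `2h/3` for apex offset
#' `h`), plus autoregressive perpendicular jitter whose amplitude is chosen
#' from an empirical calibration map so the multiscale sample entropy of
#' the distance-to-endpoint series lands near `target_se_raw`. Sample
#' count is `rt_s * rate`; positions are rounded to integer pixels in
#' screen coordinates (y down).
#'
#' Targets outside the calibration range are clamped (best effort).
#'
#' @param response `"login"` or `"back"`.
#' @param target_auc signed AUC target in normalized units (positive =
#'   toward the non-chosen alternative).
#' @param target_se_raw raw multiscale sample entropy target (> 0).
#' @param rt_s response time in seconds (> 0).
#' @param rate sampling rate in Hz.
#' @param seed optional seed (otherwise uses the current RNG stream).
#' @param start,button start and click positions in screen pixels; the
#'   login button location varies trial to trial when `button` is `NULL`,
#'   while the back button is fixed.
#' @param screen screen size in pixels.
#' @param page_load_t load timestamp in ms.
#' @param participant_id,trial_id identifiers.
#' @return a [raw_trajectory].
#' @export
gen_trajectory <- function(response, target_auc = 0, target_se_raw = 0.1,
                           rt_s = 6, rate = 60, seed = NULL,
                           start = c(960, 700), button = NULL,
                           screen = c(1920, 1080), page_load_t = 0,
                           participant_id = "p", trial_id = "t") {
  if (!is.null(seed)) set.seed(seed)
  if (rt_s <= 0 || rate <= 0) {
    pd_stop("pd_config_error", "rt_s and rate must be > 0")
  }
  if (is.null(button)) {
    button <- if (response == "login") {
      c(round(runif(1, 1250, 1650)), round(runif(1, 250, 450)))
    } else {
      c(100, 80)  # back button is fixed
    }
  }
  n <- max(8L, as.integer(round(rt_s * rate)))
  dx <- button[1] - start[1]
  dy <- button[2] - start[2]
  chord <- sqrt(dx^2 + dy^2)
  amp <- 0
  if (target_se_raw > 0) {
    amp <- jitter_amp_for_se(target_se_raw, target_auc, rate)
  }
  angle <- if (response == "login") pi / 4 else 3 * pi / 4
  alt_side <- if (response == "login") 1 else -1
  pth <- synth_path_math(n, area = target_auc, amp = amp, phi = 0.9,
                         angle = angle, alt_side = alt_side)
  # map the unit math frame onto the screen: rotate to the screen chord,
  # scale by the chord length, flip y, translate to the start position
  phi_s <- atan2(-dy, dx)  # chord angle in math coords (y flipped)
  rot <- phi_s - angle
  xr <- cos(rot) * pth$x - sin(rot) * pth$y
  yr <- sin(rot) * pth$x + cos(rot) * pth$y
  px <- round(start[1] + chord * xr)
  py <- round(start[2] - chord * yr)
  # the click lands exactly on the button
  px[n] <- button[1]
  py[n] <- button[2]
  t <- page_load_t + round(seq(0, rt_s * 1000, length.out = n))
  raw_trajectory(participant_id, trial_id, t = t, x = px, y = py,
                 page_load_t = page_load_t,
                 final_click = c(t[n], px[n], py[n]),
                 response = response, screen = screen)
}

#' Generate and write a complete synthetic study
#'
#' Produces the three input files of the pipeline (trajectory event log,
#' trials, survey) for a full synthetic study: design and covariates,
#' outcomes from the logistic truth, and one synthetic trajectory per trial
#' whose measured AUC / SE / RT approximate the generating values. Identical
#' seeds yield identical files.
#'
#' @param config a [synth_config()].
#' @param dir output directory (created if needed).
#' @param format `"csv"` or `"json"`.
#' @return list with file `paths` and the generating `table` (including
#'   truth columns), invisibly.
#' @export
gen_dataset <- function(config = synth_config(), dir, format = c("csv",
                                                                 "json")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  # warm the calibration cache outside the seeded stream for determinism
  jitter_amp_for_se(0.1, 1, config$rate)
  tab <- gen_analysis_table(config)
  trajs <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    trajs[[i]] <- gen_trajectory(
      response = tab$response[i], target_auc = tab$auc[i],
      target_se_raw = tab$se_raw[i], rt_s = tab$rt_s[i],
      rate = config$rate, screen = config$screen,
      participant_id = tab$participant_id[i], trial_id = tab$trial_id[i])
  }
  pids <- unique(tab$participant_id)
  first <- match(pids, tab$participant_id)
  cells <- site_label(rep(pd_site_types, each = 3),
                      rep(pd_auth_levels, times = 2))
  fam <- matrix(NA_integer_, length(pids), 6,
                dimnames = list(pids, paste0("familiarity_", cells)))
  for (i in seq_len(nrow(tab))) {
    fam[tab$participant_id[i],
        paste0("familiarity_", site_label(tab$site_type[i],
                                          tab$auth_level[i]))] <-
      tab$familiarity[i]
  }
  survey <- data.frame(
    participant_id = pids,
    knowledge_correct = round(tab$knowledge[first] * 10),
    indicators_correct = rbinom(length(pids), 3, 0.5),
    indicators_incorrect = rbinom(length(pids), 4, 0.3),
    fam,
    age = 18 + stats::rpois(length(pids), 13),
    gender = sample(c("female", "male", "other"), length(pids),
                    replace = TRUE, prob = c(0.41, 0.57, 0.02)),
    stringsAsFactors = FALSE, check.names = FALSE)
  trials <- data.frame(
    participant_id = tab$participant_id, trial_id = tab$trial_id,
    site_type = tab$site_type, auth_level = tab$auth_level,
    response = tab$response, usable = as.integer(tab$usable),
    stringsAsFactors = FALSE)
  ext <- if (format == "csv") ".csv" else ".json"
  paths <- list(trajectories = file.path(dir, paste0("trajectories", ext)),
                trials = file.path(dir, paste0("trials", ext)),
                survey = file.path(dir, paste0("survey", ext)))
  write_trajectories(trajs, paths$trajectories)
  write_trials(trials, paths$trials)
  write_surveys(survey, paths$survey)
  meta <- list(seed = config$seed, n_participants = config$n_participants,
               model = config$model, rate = config$rate,
               penalties_s = as.list(config$penalties_s))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(list(paths = paths, table = tab))
}
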