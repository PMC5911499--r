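#' Declarative specification of the accuracy models
#'
#' The three nested models of threat-detection accuracy share one design
#' language:
#'
#' * `two_factor` - experimental factors only: `spoof` (0 = non-spoof,
#'   1 = spoof) and `auth` (centered linear ordinal contrast, PE = -1,
#'   SV = 0, EV = +1), with interactions up to order 2.
#' * `survey_based` - adds the survey predictors `knowledge` (fraction
#'   correct) and `familiarity` (1-5 Likert), interactions up to order 3.
#' * `real_time` - further adds the mouse-tracking measures `auc`
#'   (signed-log transformed), `se` (log of raw sample entropy) and `rt`
#'   (log milliseconds), interactions up to order 3.
#'
#' Continuous predictors are transformed, then centered and scaled to unit
#' SD, so every model intercept is the log-odds of a correct response in
#' the non-spoof, standard-validation condition at average covariates.
#' Priors are robust weakly informative Student-t(3): scale 5 for
#' coefficients, 10 for the intercept, and a half-t(3, 0, 10) on the
#' between-participant intercept SD.
#'
#' @param name one of `"two_factor"`, `"survey_based"`, `"real_time"`, or
#'   `"custom"` (then supply `predictors` and `max_interaction_order`).
#' @param predictors ordered subset of
#'   `c("spoof", "auth", "knowledge", "familiarity", "auc", "se", "rt")`,
#'   plus arbitrary extra column names (treated as continuous, identity
#'   transform) for simulation studies.
#' @param max_interaction_order highest interaction order in the design.
#' @param priors list with `coef_scale`, `intercept_scale`, `df`,
#'   `sigma_scale`, `sigma_df`.
#' @return an object of class `pd_model_spec`.
#' @export
model_spec <- function(name = c("two_factor", "survey_based", "real_time",
                                "custom"),
                       predictors = NULL, max_interaction_order = NULL,
                       priors = list()) {
  name <- match.arg(name)
  defaults <- switch(name,
    two_factor = list(predictors = c("spoof", "auth"), order = 2L),
    survey_based = list(predictors = c("spoof", "auth", "knowledge",
                                       "familiarity"), order = 3L),
    real_time = list(predictors = c("spoof", "auth", "knowledge",
                                    "familiarity", "auc", "se", "rt"),
                     order = 3L),
    custom = list(predictors = predictors, order = max_interaction_order))
  predictors <- predictors %||% defaults$predictors
  order <- as.integer(max_interaction_order %||% defaults$order)
  if (is.null(predictors) || length(predictors) < 1) {
    pd_stop("pd_config_error", "custom spec needs predictors")
  }
  if (is.na(order) || order < 1) {
    pd_stop("pd_config_error", "max_interaction_order must be >= 1")
  }
  pr <- modifyList(list(coef_scale = 5, intercept_scale = 10, df = 3,
                        sigma_scale = 10, sigma_df = 3), priors)
  structure(list(name = name, predictors = predictors,
                 max_interaction_order = min(order, length(predictors)),
                 priors = pr),
            class = "pd_model_spec")
}

#' @export
print.pd_model_spec <- function(x, ...) {
  cat(sprintf("<pd_model_spec %s: %s; interactions to order %d>\n", x$name,
              paste(x$predictors, collapse = " + "),
              x$max_interaction_order))
  invisible(x)
}

# per-predictor transform applied before centering/scaling
pd_transform_raw <- function(table, pred) {
  switch(pred,
    spoof = as.numeric(table$site_type == "spoof"),
    auth = auth_contrast(table$auth_level),
    knowledge = as.numeric(table$knowledge),
    familiarity = as.numeric(table$familiarity),
    auc = signed_log(table$auc),
    se = if ("se_log" %in% names(table) && !all(is.na(table$se_log)))
           as.numeric(table$se_log) else log(table$se_raw),
    rt = log(table$rt_s * 1000),
    {
      if (!pred %in% names(table)) {
        pd_stop("pd_config_error",
                "unknown predictor '%s' not found in table", pred)
      }
      as.numeric(table[[pred]])
    })
}

pd_is_factor_pred <- function(pred) pred %in% c("spoof", "auth")

#' Build the full-factorial design matrix for a model specification
#'
#' Codes each predictor (factors as contrasts, continuous predictors
#' transformed then standardized), then forms all main effects and all
#' interaction products up to the spec's `max_interaction_order`, plus an
#' intercept. The centering/scaling constants are recorded in the returned
#' `transform` so held-out data can be projected onto exactly the same
#' scale (pass the training `transform` back in).
#'
#' Continuous transforms: `rt -> log(ms)`, `se -> log(se_raw)`,
#' `auc -> sign(a) log(1 + |a|)`; `knowledge` and `familiarity` enter
#' untransformed. Factors (`spoof`, `auth`) are never rescaled.
#'
#' Continuous predictors are scaled by `scale_sd` sample standard
#' deviations (default 2, the Gelman convention that puts a binary
#' predictor and a continuous one on comparable footing; the interaction
#' figures' normalized axes run from -1 at 2 SD below the mean to +1 at
#' 2 SD above, which is exactly this scale). Set `scale_sd = 1` for
#' classical unit-SD standardization.
#'
#' @param table analysis table with measure columns filled.
#' @param spec a [model_spec()].
#' @param transform transform metadata from a previous call, or `NULL` to
#'   estimate from `table`.
#' @param na_action `"drop"` (default: drop rows with non-finite coded
#'   values, recording them in `dropped`) or `"error"`.
#' @param scale_sd number of sample SDs mapped to one design unit.
#' @return list with `X` (matrix incl. intercept column), `labels`,
#'   `transform`, `rows` (indices of `table` kept), `dropped`.
#' @export
build_design_matrix <- function(table, spec, transform = NULL,
                                na_action = c("drop", "error"),
                                scale_sd = 2) {
  stopifnot(inherits(spec, "pd_model_spec"))
  na_action <- match.arg(na_action)
  preds <- spec$predictors
  raw <- lapply(preds, function(p) pd_transform_raw(table, p))
  names(raw) <- preds
  bad <- !Reduce(`&`, lapply(raw, is.finite))
  if (any(bad)) {
    if (na_action == "error") {
      pd_stop("pd_validation_error",
              "non-finite coded predictor values in %d row(s)", sum(bad))
    }
  }
  rows <- which(!bad)
  estimate <- is.null(transform)
  if (estimate) {
    transform <- lapply(preds, function(p) {
      if (pd_is_factor_pred(p)) return(list(center = 0, scale = 1))
      v <- raw[[p]][rows]
      s <- sd(v)
      list(center = mean(v),
           scale = if (is.finite(s) && s > 0) scale_sd * s else 1)
    })
    names(transform) <- preds
  } else {
    miss <- setdiff(preds, names(transform))
    if (length(miss)) {
      pd_stop("pd_config_error", "transform missing predictor(s): %s",
              paste(miss, collapse = ", "))
    }
  }
  coded <- vapply(preds, function(p) {
    (raw[[p]] - transform[[p]]$center) / transform[[p]]$scale
  }, numeric(length(bad)))
  coded <- matrix(coded, ncol = length(preds),
                  dimnames = list(NULL, preds))[rows, , drop = FALSE]

  cols <- list("(Intercept)" = rep(1, length(rows)))
  for (k in seq_len(spec$max_interaction_order)) {
    sets <- utils::combn(preds, k, simplify = FALSE)
    for (s in sets) {
      cols[[paste(s, collapse = ":")]] <-
        apply(coded[, s, drop = FALSE], 1, prod)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, labels = colnames(X), transform = transform, rows = rows,
       dropped = which(bad))
}
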