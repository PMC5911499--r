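#' Configuration for multiscale sample entropy
#'
#' The "multiscale" in this package is a sweep over a grid of tolerance
#' radii and embedding dimensions (not coarse-graining of the series): the
#' final value aggregates SampEn over radii expressed as fractions of the
#' series standard deviation and embedding dimensions `m`, making the
#' measure robust to the usual sensitivity of SampEn to its parameters.
#'
#' Defaults: 13 evenly spaced radii from 0.01 to 0.25 of the series SD
#' (step 0.02), `m` from 2 to 8, a Theiler window chosen per series from the
#' 1/e decay of the sample autocorrelation, and arithmetic-mean aggregation
#' over the grid cells where SampEn is defined.
#'
#' @param r_grid radii as fractions of the series SD, all in (0, 1].
#' @param m_range integer embedding dimensions, all >= 1.
#' @param theiler rule for the minimum temporal separation of compared
#'   templates; `"acf_1e"` (lag at which autocorrelation drops to 1/e,
#'   capped at N/10) or `"none"` (window 1, i.e. only self-matches excluded).
#' @param aggregation how to combine defined grid cells; only `"mean"` is
#'   implemented.
#' @param resample if `TRUE`, linearly resample unevenly spaced series to a
#'   uniform grid of the same length before computing entropy (off by
#'   default; the measures operate on the recorded samples).
#' @return an object of class `entropy_config`.
#' @export
entropy_config <- function(r_grid = seq(0.01, 0.25, by = 0.02),
                           m_range = 2:8,
                           theiler = c("acf_1e", "none"),
                           aggregation = c("mean"),
                           resample = FALSE) {
  theiler <- match.arg(theiler)
  aggregation <- match.arg(aggregation)
  if (length(r_grid) < 1 || any(r_grid <= 0 | r_grid > 1)) {
    pd_stop("pd_config_error", "r_grid fractions must lie in (0, 1]")
  }
  m_range <- as.integer(m_range)
  if (length(m_range) < 1 || any(m_range < 1)) {
    pd_stop("pd_config_error", "m_range must be integers >= 1")
  }
  structure(list(r_grid = as.numeric(r_grid), m_range = sort(m_range),
                 theiler = theiler, aggregation = aggregation,
                 resample = isTRUE(resample)),
            class = "entropy_config")
}

#' Sample entropy of a scalar series
#'
#' SampEn(m, r) = -ln(A/B), where `B` counts pairs of length-`m` templates
#' whose Chebyshev distance is at most `r`, and `A` counts the same for
#' length-`m+1` templates. Template starts run over the first `N - m`
#' positions (Richman-Moorman convention, so a constant series gives
#' exactly 0), self-matches are excluded, and pairs closer in time than the
#' Theiler window `w` (`|i - j| < w`) are excluded from both counts.
#'
#' When no template pairs match (`A = 0` or `B = 0`) the value is undefined
#' and `NA` is returned rather than an error, so grid sweeps can skip such
#' cells.
#'
#' @param x numeric series, length `N > m + 1`.
#' @param m embedding dimension (template length), >= 1.
#' @param r absolute tolerance radius, > 0.
#' @param w Theiler window, >= 1 (1 = exclude self-matches only).
#' @return non-negative number, or `NA_real_` if undefined.
#' @export
#' @examples
#' set.seed(1)
#' sample_entropy(runif(300), m = 2, r = 0.2 * sd(runif(300)), w = 1)
sample_entropy <- function(x, m, r, w = 1L) {
  x <- as.numeric(x)
  n <- length(x)
  m <- as.integer(m)
  if (m < 1) pd_stop("pd_config_error", "m must be >= 1")
  if (n <= m + 1) {
    pd_stop("pd_series_error", "series too short (N = %d) for m = %d", n, m)
  }
  if (!is.finite(r) || r <= 0) pd_stop("pd_config_error", "r must be > 0")
  w <- max(1L, as.integer(w))
  cnt <- .sampen_counts_cpp(x, m, m, r, w)
  b <- cnt[1, 1]; a <- cnt[1, 2]
  if (a == 0 || b == 0) return(NA_real_)
  -log(a / b)
}

#' Theiler window from the autocorrelation decay
#'
#' Smallest lag at which the sample autocorrelation of the series falls to
#' 1/e or below, capped at `floor(N/10)` and bounded below by 1. Template
#' pairs closer in time than this window are trivially similar (dynamical
#' neighbors along the trajectory rather than genuine recurrences) and are
#' excluded from the sample-entropy match counts.
#'
#' @param x numeric series, length >= 10.
#' @return positive integer lag.
#' @export
theiler_window <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10) pd_stop("pd_series_error", "need N >= 10 for Theiler window")
  cap <- max(1L, n %/% 10L)
  if (sd(x) == 0) return(1L)
  rho <- as.vector(acf(x, lag.max = cap, plot = FALSE,
                       demean = TRUE)$acf)[-1]
  hit <- which(rho <= exp(-1))
  if (length(hit) == 0) cap else min(hit[1], cap)
}

#' Multiscale sample entropy over a radius x dimension grid
#'
#' Evaluates [sample_entropy()] on the full grid of `r_grid * sd(x)` radii
#' and `m_range` embedding dimensions, with the series' own
#' [theiler_window()], and aggregates the defined cells (by default their
#' arithmetic mean). Returns both the aggregated raw value `se_raw` and its
#' natural log `se_log`, which is the scale used in the regression models.
#'
#' Degenerate cases: a constant series has `se_raw = 0` and an undefined
#' (`NA`) log, flagged via `log_defined = FALSE`; if every grid cell is
#' undefined an error of class `pd_entropy_error` is raised.
#'
#' @param x numeric series; must satisfy `N > max(m_range) + 1`.
#' @param config an [entropy_config()].
#' @param t optional sample times, used only when `config$resample` is
#'   `TRUE`.
#' @return list with `se_raw`, `se_log`, `log_defined`, `n_defined`,
#'   `n_cells`, `theiler`, and the `grid` of per-cell values.
#' @export
multiscale_sample_entropy <- function(x, config = entropy_config(),
                                      t = NULL) {
  stopifnot(inherits(config, "entropy_config"))
  x <- as.numeric(x)
  n <- length(x)
  m_max <- max(config$m_range)
  if (n <= m_max + 1) {
    pd_stop("pd_series_error",
            "series too short (N = %d) for max m = %d", n, m_max)
  }
  if (config$resample && !is.null(t)) {
    x <- stats::approx(t, x, xout = seq(min(t), max(t), length.out = n))$y
  }
  s <- sd(x)
  if (s == 0) {
    return(list(se_raw = 0, se_log = NA_real_, log_defined = FALSE,
                n_defined = 0L, n_cells = 0L, theiler = 1L, grid = NULL))
  }
  w <- if (config$theiler == "acf_1e") theiler_window(x) else 1L
  m_min <- min(config$m_range)
  grid <- matrix(NA_real_, nrow = length(config$r_grid),
                 ncol = m_max - m_min + 1,
                 dimnames = list(r = config$r_grid, m = m_min:m_max))
  for (k in seq_along(config$r_grid)) {
    cnt <- .sampen_counts_cpp(x, m_min, m_max, config$r_grid[k] * s, w)
    b <- cnt[, 1]; a <- cnt[, 2]
    val <- ifelse(a > 0 & b > 0, -log(a / b), NA_real_)
    grid[k, ] <- val
  }
  keep <- m_min:m_max %in% config$m_range
  cells <- grid[, keep, drop = FALSE]
  defined <- is.finite(cells)
  if (!any(defined)) {
    pd_stop("pd_entropy_error", "all (r, m) grid cells undefined")
  }
  se_raw <- mean(cells[defined])
  log_ok <- is.finite(se_raw) && se_raw > 0
  list(se_raw = se_raw,
       se_log = if (log_ok) log(se_raw) else NA_real_,
       log_defined = log_ok,
       n_defined = sum(defined), n_cells = length(cells),
       theiler = w, grid = cells)
}
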