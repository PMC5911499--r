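#' Normalize a mouse trajectory to the canonical unit frame
#'
#' Applies a similarity transform (translation, single y-axis flip from
#' screen to mathematical coordinates, uniform scaling, rotation) so that
#' the path starts at the origin and the final response click lies at unit
#' distance from the origin, on the 45 degree ray for `login` responses and
#' the 135 degree ray for `back` responses. This puts trajectories recorded
#' on arbitrary screens and button layouts into one comparable state space
#' in which the ideal straight-line response has length 1.
#'
#' The final click position is appended as the terminal sample when it
#' differs from the last recorded sample. Timestamps are carried through
#' unchanged; nothing is resampled.
#'
#' @param raw a [raw_trajectory] with a non-`NA` `response`.
#' @return an object of class `normalized_trajectory`: list with `t`, `x`,
#'   `y`, `response`, `participant_id`, `trial_id`.
#' @export
#' @examples
#' tr <- raw_trajectory("p", "t", t = c(0, 50, 100), x = c(10, 40, 60),
#'                      y = c(500, 480, 450), page_load_t = 0,
#'                      final_click = c(120, 80, 430), response = "login")
#' nt <- normalize_trajectory(tr)
#' sqrt(nt$x[length(nt$x)]^2 + nt$y[length(nt$y)]^2)  # 1
normalize_trajectory <- function(raw) {
  if (is.na(raw$response) || !raw$response %in% pd_responses) {
    pd_stop("pd_validation_error",
            "trajectory %s/%s has no response; join with the trials table",
            raw$participant_id, raw$trial_id)
  }
  x <- raw$x
  y <- raw$y
  fc <- raw$final_click
  n <- length(x)
  if (fc[2] != x[n] || fc[3] != y[n]) {
    x <- c(x, fc[2]); y <- c(y, fc[3])
    t <- c(raw$t, fc[1])
  } else {
    t <- raw$t
  }
  # translate to start, flip screen y to math y
  xs <- x - x[1]
  ys <- -(y - y[1])
  n <- length(xs)
  chord <- sqrt(xs[n]^2 + ys[n]^2)
  if (chord <= 0) {
    pd_stop("pd_degenerate_error",
            "trajectory %s/%s: zero-length chord (start == end)",
            raw$participant_id, raw$trial_id)
  }
  xs <- xs / chord
  ys <- ys / chord
  target <- if (raw$response == "login") pi / 4 else 3 * pi / 4
  theta <- target - atan2(ys[n], xs[n])
  ct <- cos(theta); st <- sin(theta)
  structure(list(t = t,
                 x = ct * xs - st * ys,
                 y = st * xs + ct * ys,
                 response = raw$response,
                 participant_id = raw$participant_id,
                 trial_id = raw$trial_id),
            class = "normalized_trajectory")
}

#' @export
print.normalized_trajectory <- function(x, ...) {
  cat(sprintf("<normalized_trajectory %s/%s: %d samples, response=%s>\n",
              x$participant_id %||% "?", x$trial_id %||% "?",
              length(x$x), x$response))
  invisible(x)
}

#' Signed area between a trajectory and its chord
#'
#' Shoelace (signed polygon) area of the closed curve formed by the
#' normalized trajectory followed by the reversed straight chord from end to
#' start. The sign convention is behavioral: positive area means net spatial
#' deviation toward the *non-chosen* alternative's side of the chord (the
#' back-button side for `login` responses and vice versa), i.e. attraction
#' toward the competing response. A chord-sampled straight path has area 0.
#'
#' AUC is purely spatial; timestamps are ignored.
#'
#' @param traj a `normalized_trajectory` (any frame works, but the canonical
#'   unit frame gives the dimensionless value used in modeling).
#' @return signed dimensionless area.
#' @export
compute_auc <- function(traj) {
  x <- traj$x
  y <- traj$y
  n <- length(x)
  if (n < 2) pd_stop("pd_validation_error", "need >= 2 samples for AUC")
  # cyclic shoelace sum over path vertices; closing edge = reversed chord
  xn <- c(x, x[1])
  yn <- c(y, y[1])
  shoelace <- 0.5 * sum(xn[-(n + 1)] * yn[-1] - xn[-1] * yn[-(n + 1)])
  # shoelace > 0 is counter-clockwise = deviation to the right of the chord
  # direction; the non-chosen alternative sits to the left for login
  # (135 deg is left of 45 deg) and to the right for back responses.
  if (traj$response == "login") -shoelace else shoelace
}

#' Response time of a trial
#'
#' Time between the login page first appearing (the `load` event) and the
#' final response click, in seconds.
#'
#' @param raw a [raw_trajectory].
#' @return positive number of seconds.
#' @export
compute_rt <- function(raw) {
  rt <- (raw$final_click[1] - raw$page_load_t) / 1000
  if (!is.finite(rt) || rt <= 0) {
    pd_stop("pd_validation_error",
            "trial %s/%s: final click must occur after page load",
            raw$participant_id, raw$trial_id)
  }
  rt
}

#' Distance-to-endpoint series of a trajectory
#'
#' Euclidean distance of every sample from the final sample (the response
#' click). This scalar series captures both x and y motion and is the input
#' to the sample-entropy measures; it is invariant to the rotation used in
#' normalization (distances are preserved by isometries).
#'
#' @param traj a `normalized_trajectory` (or any list with `x`, `y`).
#' @return numeric vector, same length as the sample count; last value 0.
#' @export
distance_to_endpoint_series <- function(traj) {
  n <- length(traj$x)
  if (n < 2) pd_stop("pd_validation_error", "need >= 2 samples")
  sqrt((traj$x - traj$x[n])^2 + (traj$y - traj$y[n])^2)
}

#' Fill the real-time measure columns of an analysis table
#'
#' Runs [normalize_trajectory()], [compute_auc()], [compute_rt()] and
#' [multiscale_sample_entropy()] (on the distance-to-endpoint series) for
#' every row of the analysis table, writing columns `auc`, `rt_s`, `se_raw`
#' and `se_log`. Trials whose entropy is undefined (e.g. constant distance
#' series) keep `NA` in `se_log` and are reported via a warning.
#'
#' @param table analysis table from [build_analysis_table()].
#' @param trajectories named list from [read_trajectories()].
#' @param config an [entropy_config()].
#' @return the table with measure columns filled.
#' @export
compute_measures <- function(table, trajectories, config = entropy_config()) {
  keys <- vapply(trajectories, function(tr)
    trial_key(tr$participant_id, tr$trial_id), character(1))
  idx <- match(trial_key(table$participant_id, table$trial_id), keys)
  if (anyNA(idx)) {
    pd_stop("pd_join_error", "missing trajectory for trial(s): %s",
            paste(table$trial_id[is.na(idx)][1:min(5, sum(is.na(idx)))],
                  collapse = ", "))
  }
  n_undef <- 0L
  for (i in seq_len(nrow(table))) {
    tr <- trajectories[[idx[i]]]
    tr$response <- table$response[i]
    nt <- normalize_trajectory(tr)
    table$auc[i] <- compute_auc(nt)
    table$rt_s[i] <- compute_rt(tr)
    d <- distance_to_endpoint_series(nt)
    se <- tryCatch(multiscale_sample_entropy(d, config),
                   pd_entropy_error = function(e) NULL)
    if (is.null(se)) {
      n_undef <- n_undef + 1L
    } else {
      table$se_raw[i] <- se$se_raw
      table$se_log[i] <- se$se_log
      if (is.na(se$se_log)) n_undef <- n_undef + 1L
    }
  }
  if (n_undef > 0) {
    warning(sprintf("sample entropy undefined for %d trial(s); se_log is NA",
                    n_undef))
  }
  table
}
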