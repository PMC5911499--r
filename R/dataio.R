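## File schemas
##
## trajectory log (CSV or JSON): one row per mouse event,
##   participant_id, trial_id, t_ms, x_px, y_px, event in {load, move, click},
##   screen_w, screen_h (optional, default 1920x1080).
##   Exactly one load (defines t = 0 reference) and one terminal click per
##   trial; `t_ms` non-decreasing within a trial.
## trials: participant_id, trial_id, site_type in {non_spoof, spoof},
##   auth_level in {PE, SV, EV}, response in {login, back}; optional `usable`
##   flag (0/1) marking trials excluded from analysis.
## survey: participant_id, knowledge_correct (0-10), indicators_correct,
##   indicators_incorrect, familiarity_<site> for the six
##   site-type x auth-level cells, age, gender.

#' Construct a raw mouse trajectory for one trial
#'
#' A `raw_trajectory` holds timestamped screen-pixel mouse samples for a
#' single trial, together with the page-load event that defines `t = 0` and
#' the final response click. Positions use the screen convention: origin at
#' the top-left corner, y increasing downward. The y-axis flip to
#' mathematical coordinates happens once, inside [normalize_trajectory()].
#'
#' @param participant_id,trial_id opaque identifier strings.
#' @param t,x,y integer vectors: sample times (ms) and positions (px).
#' @param page_load_t page-load time in ms (defines the RT clock start).
#' @param final_click length-3 numeric `(t, x, y)` of the response click.
#' @param response `"login"` or `"back"`.
#' @param screen length-2 numeric `(width, height)` in pixels.
#' @return an object of class `raw_trajectory`.
#' @export
raw_trajectory <- function(participant_id, trial_id, t, x, y, page_load_t,
                           final_click, response, screen = c(1920, 1080)) {
  obj <- structure(
    list(participant_id = as.character(participant_id),
         trial_id = as.character(trial_id),
         t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
         page_load_t = as.numeric(page_load_t),
         final_click = as.numeric(final_click),
         response = as.character(response), screen = as.numeric(screen)),
    class = "raw_trajectory")
  validate_raw_trajectory(obj)
  obj
}

#' Validate a raw trajectory's invariants
#'
#' Checks sample count, timestamp monotonicity, the ordering of the
#' page-load and final-click events, and that the click lies on screen.
#' Called by [raw_trajectory()] and by the file readers.
#'
#' @param traj a `raw_trajectory`.
#' @return the object, invisibly; errors with class
#'   `pd_validation_error` on violation.
#' @export
validate_raw_trajectory <- function(traj) {
  id <- paste0(traj$participant_id, "/", traj$trial_id)
  n <- length(traj$t)
  if (n < 2 || length(traj$x) != n || length(traj$y) != n) {
    pd_stop("pd_validation_error",
            "trial %s: needs >= 2 samples with matching x/y", id)
  }
  if (any(diff(traj$t) < 0)) {
    pd_stop("pd_validation_error",
            "trial %s: decreasing timestamps within trial", id)
  }
  if (!is.na(traj$response) && !traj$response %in% pd_responses) {
    pd_stop("pd_validation_error", "trial %s: invalid response '%s'",
            id, traj$response)
  }
  if (length(traj$final_click) != 3 || traj$final_click[1] < traj$t[n]) {
    pd_stop("pd_validation_error",
            "trial %s: final click must be at/after last sample", id)
  }
  fc <- traj$final_click
  if (fc[2] < 0 || fc[2] > traj$screen[1] || fc[3] < 0 ||
      fc[3] > traj$screen[2]) {
    pd_stop("pd_validation_error",
            "trial %s: final click outside screen bounds", id)
  }
  if (traj$page_load_t > traj$t[1]) {
    pd_stop("pd_validation_error",
            "trial %s: page load must precede first sample", id)
  }
  invisible(traj)
}

#' @export
print.raw_trajectory <- function(x, ...) {
  cat(sprintf("<raw_trajectory %s/%s: %d samples, response=%s, rt=%.2fs>\n",
              x$participant_id, x$trial_id, length(x$t), x$response,
              (x$final_click[1] - x$page_load_t) / 1000))
  invisible(x)
}

trial_key <- function(pid, tid) paste(pid, tid, sep = "\r")

read_table_any <- function(path) {
  if (!file.exists(path)) pd_stop("pd_io_error", "file not found: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    data.table::fread(path, data.table = FALSE, colClasses = NULL)
  }
}

write_table_any <- function(df, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "columns", digits = NA)
  } else {
    data.table::fwrite(df, path)
  }
  invisible(path)
}

#' Read a trajectory event log
#'
#' Parses the trajectory CSV (or its JSON mirror) into a list of
#' [raw_trajectory] objects, one per `(participant_id, trial_id)` pair, and
#' enforces all trajectory invariants. The `load` event sets `page_load_t`;
#' `move` and `click` rows become the sample path, with the single terminal
#' `click` also recorded as `final_click`. The response (`login` vs `back`)
#' is not part of this file; it is attached from the trials table, so
#' trajectories read in isolation carry `response = NA` until joined.
#'
#' @param path file path (`.csv` or `.json`).
#' @param responses optional data frame with columns `participant_id`,
#'   `trial_id`, `response` used to annotate each trajectory (normally the
#'   trials table from [read_trials()]).
#' @return a named list of `raw_trajectory` objects keyed
#'   `"<participant_id>/<trial_id>"`.
#' @export
read_trajectories <- function(path, responses = NULL) {
  df <- read_table_any(path)
  need <- c("participant_id", "trial_id", "t_ms", "x_px", "y_px", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    pd_stop("pd_schema_error", "trajectory log missing column(s): %s",
            paste(miss, collapse = ", "))
  }
  bad_ev <- which(!df$event %in% c("load", "move", "click"))
  if (length(bad_ev)) {
    pd_stop("pd_schema_error", "malformed row %d: unknown event '%s'",
            bad_ev[1], df$event[bad_ev[1]])
  }
  for (col in c("t_ms", "x_px", "y_px")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      pd_stop("pd_schema_error", "malformed row %d: non-numeric %s",
              which(is.na(v))[1], col)
    }
    df[[col]] <- v
  }
  if (!"screen_w" %in% names(df)) df$screen_w <- 1920
  if (!"screen_h" %in% names(df)) df$screen_h <- 1080

  resp_map <- NULL
  if (!is.null(responses)) {
    resp_map <- setNames(as.character(responses$response),
                         trial_key(responses$participant_id,
                                   responses$trial_id))
  }
  groups <- split(df, trial_key(df$participant_id, df$trial_id))
  out <- lapply(groups, function(gr) {
    id <- paste0(gr$participant_id[1], "/", gr$trial_id[1])
    if (any(diff(gr$t_ms) < 0)) {
      pd_stop("pd_validation_error", "trial %s: decreasing timestamps", id)
    }
    if (sum(gr$event == "load") != 1L) {
      pd_stop("pd_validation_error", "trial %s: expected exactly one load event", id)
    }
    clicks <- which(gr$event == "click")
    if (length(clicks) != 1L || clicks != nrow(gr)) {
      pd_stop("pd_validation_error",
              "trial %s: expected exactly one terminal click event", id)
    }
    samp <- gr[gr$event != "load", , drop = FALSE]
    key <- trial_key(gr$participant_id[1], gr$trial_id[1])
    resp <- if (!is.null(resp_map)) resp_map[[key]] %||% NA_character_ else NA_character_
    obj <- structure(
      list(participant_id = as.character(gr$participant_id[1]),
           trial_id = as.character(gr$trial_id[1]),
           t = samp$t_ms, x = samp$x_px, y = samp$y_px,
           page_load_t = gr$t_ms[gr$event == "load"],
           final_click = c(samp$t_ms[nrow(samp)], samp$x_px[nrow(samp)],
                           samp$y_px[nrow(samp)]),
           response = resp,
           screen = c(gr$screen_w[1], gr$screen_h[1])),
      class = "raw_trajectory")
    validate_raw_trajectory(obj)
    obj
  })
  names(out) <- vapply(out, function(tr)
    paste0(tr$participant_id, "/", tr$trial_id), character(1))
  out
}

#' Write trajectories back to the event-log schema
#'
#' Inverse of [read_trajectories()]; write-then-read is an identity (exact
#' for integer-valued times/positions).
#'
#' @param trajectories list of `raw_trajectory` objects.
#' @param path output path (`.csv` or `.json`).
#' @return the path, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  rows <- lapply(trajectories, function(tr) {
    n <- length(tr$t)
    # terminal sample is the click; preceding samples are moves
    data.frame(
      participant_id = tr$participant_id, trial_id = tr$trial_id,
      t_ms = c(tr$page_load_t, tr$t),
      x_px = c(tr$x[1], tr$x), y_px = c(tr$y[1], tr$y),
      event = c("load", rep("move", n - 1), "click"),
      screen_w = tr$screen[1], screen_h = tr$screen[2],
      stringsAsFactors = FALSE)
  })
  write_table_any(data.table::rbindlist(rows), path)
}

#' Read the trials table
#'
#' @param path file path (`.csv` or `.json`) with columns `participant_id`,
#'   `trial_id`, `site_type`, `auth_level`, `response` and optionally
#'   `usable`.
#' @return a data frame with an added `usable` column (default `TRUE`).
#' @export
read_trials <- function(path) {
  df <- read_table_any(path)
  need <- c("participant_id", "trial_id", "site_type", "auth_level",
            "response")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    pd_stop("pd_schema_error", "trials missing column(s): %s",
            paste(miss, collapse = ", "))
  }
  for (col in c("participant_id", "trial_id")) df[[col]] <- as.character(df[[col]])
  bad <- which(!df$site_type %in% pd_site_types)
  if (length(bad)) {
    pd_stop("pd_schema_error", "row %d: invalid site_type '%s'", bad[1],
            df$site_type[bad[1]])
  }
  bad <- which(!df$auth_level %in% pd_auth_levels)
  if (length(bad)) {
    pd_stop("pd_schema_error", "row %d: invalid auth_level '%s'", bad[1],
            df$auth_level[bad[1]])
  }
  bad <- which(!df$response %in% pd_responses)
  if (length(bad)) {
    pd_stop("pd_schema_error", "row %d: invalid response '%s'", bad[1],
            df$response[bad[1]])
  }
  df$usable <- if ("usable" %in% names(df)) as.logical(df$usable) else TRUE
  df
}

#' @rdname read_trials
#' @param trials data frame in the trials schema.
#' @export
write_trials <- function(trials, path) write_table_any(trials, path)

#' Read the survey table
#'
#' @param path file path (`.csv` or `.json`).
#' @return a data frame; `knowledge_correct` is validated to lie in 0..10.
#' @export
read_surveys <- function(path) {
  df <- read_table_any(path)
  need <- c("participant_id", "knowledge_correct", "indicators_correct",
            "indicators_incorrect")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    pd_stop("pd_schema_error", "survey missing column(s): %s",
            paste(miss, collapse = ", "))
  }
  df$participant_id <- as.character(df$participant_id)
  if (any(df$knowledge_correct < 0 | df$knowledge_correct > 10)) {
    pd_stop("pd_schema_error", "knowledge_correct outside 0..10")
  }
  if (anyDuplicated(df$participant_id)) {
    pd_stop("pd_schema_error", "duplicate survey rows for participant(s): %s",
            paste(unique(df$participant_id[duplicated(df$participant_id)]),
                  collapse = ", "))
  }
  df
}

#' @rdname read_surveys
#' @param surveys data frame in the survey schema.
#' @export
write_surveys <- function(surveys, path) write_table_any(surveys, path)

#' Flag participants that gave only one type of response
#'
#' Mirrors the exclusion rule used to define the reduced analysis sample:
#' participants who answered `login` (or `back`) on every trial carry no
#' information about discrimination and can optionally be excluded.
#' This is a flagging operation; nothing is deleted.
#'
#' @param trials trials data frame.
#' @return data frame with `participant_id` and logical `single_response`.
#' @export
flag_single_response <- function(trials) {
  tab <- tapply(trials$response, trials$participant_id,
                function(r) length(unique(r)) == 1L)
  data.frame(participant_id = names(tab),
             single_response = as.vector(tab),
             stringsAsFactors = FALSE)
}

#' Join trajectories, trials and surveys into the per-trial analysis table
#'
#' Produces one row per usable trial with condition codes, the observed
#' response and its correctness, and the survey-derived predictors
#' (knowledge, indicator score, per-site familiarity). The real-time
#' measure columns (`auc`, `se_raw`, `se_log`, `rt_s`) are initialized to
#' `NA` and filled by [compute_measures()].
#'
#' @param trajectories named list from [read_trajectories()] (or `NULL` to
#'   skip the trajectory-completeness check).
#' @param trials data frame from [read_trials()].
#' @param surveys data frame from [read_surveys()].
#' @param drop_unusable drop trials flagged `usable = FALSE`? Default `TRUE`.
#' @param exclude_single_response drop all trials of participants flagged by
#'   [flag_single_response()]? Default `FALSE` (the full sample).
#' @return a data frame, 6 rows per (complete) participant.
#' @export
build_analysis_table <- function(trajectories, trials, surveys,
                                 drop_unusable = TRUE,
                                 exclude_single_response = FALSE) {
  if (!is.null(trajectories)) {
    have <- vapply(trajectories, function(tr)
      trial_key(tr$participant_id, tr$trial_id), character(1))
    want <- trial_key(trials$participant_id, trials$trial_id)
    miss <- setdiff(want, have)
    if (length(miss)) {
      pd_stop("pd_join_error", "trial(s) without trajectory: %s",
              paste(gsub("\r", "/", head(miss, 5)), collapse = ", "))
    }
  }
  orphan <- setdiff(trials$participant_id, surveys$participant_id)
  if (length(orphan)) {
    pd_stop("pd_join_error", "no survey record for participant(s): %s",
            paste(unique(orphan), collapse = ", "))
  }
  sidx <- match(trials$participant_id, surveys$participant_id)
  site <- site_label(trials$site_type, trials$auth_level)
  fam_cols <- paste0("familiarity_", site)
  miss_fam <- setdiff(unique(fam_cols), names(surveys))
  if (length(miss_fam)) {
    pd_stop("pd_schema_error", "survey missing familiarity column(s): %s",
            paste(miss_fam, collapse = ", "))
  }
  fam <- vapply(seq_len(nrow(trials)), function(i)
    as.numeric(surveys[[fam_cols[i]]][sidx[i]]), numeric(1))
  if (any(!fam %in% 1:5)) {
    pd_stop("pd_validation_error", "familiarity values must be integers 1..5")
  }
  tab <- data.frame(
    participant_id = trials$participant_id,
    trial_id = trials$trial_id,
    site_type = trials$site_type,
    auth_level = trials$auth_level,
    response = trials$response,
    accuracy = response_correct(trials$site_type, trials$response),
    usable = trials$usable,
    knowledge = surveys$knowledge_correct[sidx] / 10,
    indicator_score = score_indicators(surveys$indicators_correct[sidx],
                                       surveys$indicators_incorrect[sidx]),
    familiarity = fam,
    auc = NA_real_, se_raw = NA_real_, se_log = NA_real_, rt_s = NA_real_,
    stringsAsFactors = FALSE)
  if (exclude_single_response) {
    fl <- flag_single_response(trials)
    drop_ids <- fl$participant_id[fl$single_response]
    tab <- tab[!tab$participant_id %in% drop_ids, , drop = FALSE]
  }
  if (drop_unusable) tab <- tab[tab$usable, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
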