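#' Signed logarithmic transform
#'
#' `signed_log(a) = sign(a) * log(1 + |a|)`, the symmetric log transform used
#' to bring heavily skewed signed quantities (such as trajectory AUC) onto a
#' roughly symmetric modeling scale. `inv_signed_log()` is its exact inverse.
#'
#' @param a numeric vector.
#' @return transformed numeric vector of the same length.
#' @export
#' @examples
#' signed_log(c(-8, 0, 8))
#' inv_signed_log(signed_log(2.5))
signed_log <- function(a) sign(a) * log1p(abs(a))

#' @rdname signed_log
#' @export
inv_signed_log <- function(a) sign(a) * expm1(abs(a))

# stop() with a condition class so callers can test errors precisely
pd_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "pd_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Levels used throughout; authentication is ordinal PE < SV < EV.
pd_auth_levels <- c("PE", "SV", "EV")
pd_site_types <- c("non_spoof", "spoof")
pd_responses <- c("login", "back")

# centered linear ordinal contrast for authentication level
auth_contrast <- function(auth_level) {
  idx <- match(auth_level, pd_auth_levels)
  if (anyNA(idx)) {
    pd_stop("pd_schema_error", "invalid auth_level value(s): %s",
            paste(unique(auth_level[is.na(idx)]), collapse = ", "))
  }
  c(-1, 0, 1)[idx]
}

# site label joining trials to survey familiarity columns
site_label <- function(site_type, auth_level) {
  paste0(site_type, "_", tolower(auth_level))
}

# accuracy invariant: correct = login on non-spoof, back on spoof
response_correct <- function(site_type, response) {
  as.integer((site_type == "non_spoof" & response == "login") |
               (site_type == "spoof" & response == "back"))
}
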