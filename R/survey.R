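#' Security-indicator score
#'
#' Ratio score for self-reported use of browser security indicators:
#' `(n_correct + 1) / (n_incorrect + 1)`. With the default option counts
#' (3 correct indicators and 4 incorrect distractors, inferred from the
#' attainable score range 0.2 to 4.0) the score spans exactly
#' `[0.2, 4.0]`, is strictly increasing in the number of correct
#' identifications and strictly decreasing in the number of incorrect ones.
#' A respondent who selects nothing scores the neutral 1.0.
#'
#' The indicator score is descriptive only; it is not used as a predictor
#' in any of the fitted models.
#'
#' @param n_correct,n_incorrect integer counts of correctly and incorrectly
#'   identified indicators (vectorized).
#' @param max_correct,max_incorrect option counts available in the survey.
#' @return numeric score(s) in `[1/(max_incorrect+1), max_correct+1]`.
#' @export
#' @examples
#' score_indicators(3, 0)  # 4.0
#' score_indicators(0, 4)  # 0.2
score_indicators <- function(n_correct, n_incorrect, max_correct = 3,
                             max_incorrect = 4) {
  if (any(n_correct < 0 | n_correct > max_correct)) {
    pd_stop("pd_validation_error", "n_correct outside 0..%d", max_correct)
  }
  if (any(n_incorrect < 0 | n_incorrect > max_incorrect)) {
    pd_stop("pd_validation_error", "n_incorrect outside 0..%d", max_incorrect)
  }
  (n_correct + 1) / (n_incorrect + 1)
}

#' Security-knowledge score
#'
#' Fraction correct over a 10-item multiple-choice quiz on formal
#' information-security knowledge; values fall on the 0.1 grid in `[0, 1]`.
#'
#' @param answers logical (or 0/1) vector of exactly 10 item-correctness
#'   indicators.
#' @return fraction in `[0, 1]`.
#' @export
score_knowledge <- function(answers) {
  if (length(answers) != 10 || anyNA(answers)) {
    pd_stop("pd_validation_error", "knowledge quiz must have exactly 10 items")
  }
  mean(as.logical(answers))
}
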