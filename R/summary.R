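#' Response rate as a printed percentage
#'
#' `100 * n_completed / n_invited`, rounded half away from zero to one
#' decimal — the convention used for published participation figures
#' (e.g. 113 of 500 invited is 22.6).
#'
#' @param n_invited number invited (> 0).
#' @param n_completed number who completed (0 <= n_completed <= n_invited).
#' @return percentage with one decimal.
#' @examples
#' response_rate(500, 113)  # 22.6
#' response_rate(113, 85)   # 75.2
#' @export
response_rate <- function(n_invited, n_completed) {
  if (any(n_invited <= 0)) abort("`n_invited` must be positive")
  if (any(n_completed < 0)) abort("`n_completed` must be non-negative")
  if (any(n_completed > n_invited)) {
    abort("`n_completed` cannot exceed `n_invited`")
  }
  round_half_up(100 * n_completed / n_invited, 1)
}

#' Cohort flow summary
#'
#' Collects the participant-flow counts of a two-phase crowd-sourcing
#' study — open-ended idea collection followed by scoring — and derives
#' the percentages a flow diagram reports.
#'
#' @param n_invited_phase1 clinicians invited to the idea-collection
#'   questionnaire.
#' @param n_respondents completed questionnaires.
#' @param n_raw_problems,n_raw_solutions free-text ideas collected.
#' @param n_collated_problems,n_collated_solutions distinct suggestions
#'   after thematic merging (an upstream human step; counts are inputs).
#' @param n_invited_scoring clinicians invited to score.
#' @param n_completed_sheets fully completed scoring sheets.
#' @return object of class `cohort_summary`: the counts plus
#'   `response_rate_phase1` and `scoring_return_rate` (1-decimal
#'   percentages).
#' @examples
#' cohort_summary(500, 113, 175, 147, 48, 45, 168, 57)
#' @export
cohort_summary <- function(n_invited_phase1, n_respondents,
                           n_raw_problems, n_raw_solutions,
                           n_collated_problems, n_collated_solutions,
                           n_invited_scoring, n_completed_sheets) {
  counts <- c(
    n_invited_phase1 = n_invited_phase1, n_respondents = n_respondents,
    n_raw_problems = n_raw_problems, n_raw_solutions = n_raw_solutions,
    n_collated_problems = n_collated_problems,
    n_collated_solutions = n_collated_solutions,
    n_invited_scoring = n_invited_scoring,
    n_completed_sheets = n_completed_sheets
  )
  if (any(counts < 0)) abort("all counts must be non-negative")
  structure(
    c(as.list(counts), list(
      response_rate_phase1 = response_rate(n_invited_phase1, n_respondents),
      scoring_return_rate = response_rate(n_invited_scoring,
                                          n_completed_sheets)
    )),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  cat(sprintf("  phase 1: %d invited, %d responded (%.1f%%)\n",
              x$n_invited_phase1, x$n_respondents, x$response_rate_phase1))
  cat(sprintf("  ideas: %d problems + %d solutions, collated to %d + %d\n",
              x$n_raw_problems, x$n_raw_solutions,
              x$n_collated_problems, x$n_collated_solutions))
  cat(sprintf("  scoring: %d invited, %d completed sheets (%.1f%%)\n",
              x$n_invited_scoring, x$n_completed_sheets,
              x$scoring_return_rate))
  invisible(x)
}
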