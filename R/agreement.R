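#' Modal response fraction
#'
#' Fraction of scorers giving the most frequent response to one
#' (suggestion, criterion) question.  All four codes — including
#' `"unaware"` — count as valid response categories, so widespread
#' unawareness lowers agreement on the other codes rather than inflating
#' it.  When two codes tie for most frequent the shared maximum count is
#' used; no winner needs to be picked.
#'
#' @param responses non-empty character vector of response codes.
#' @return the modal fraction, a proportion in (0, 1].
#' @examples
#' mode_fraction(c("yes", "yes", "yes", "no", "unsure"))  # 0.6
#' @export
mode_fraction <- function(responses) {
  if (length(responses) == 0) abort("no scorers: `responses` must be non-empty")
  responses <- as_response_code(responses)
  max(tabulate(factor(responses, levels = response_codes()))) / length(responses)
}

#' Average Expert Agreement (AEA)
#'
#' Per suggestion, AEA is the mean over the criteria in the set of the
#' modal response fraction: for each criterion, the number of scorers who
#' gave the most frequent response divided by the total number of scorers,
#' averaged over criteria.  AEA of 1 means every criterion was answered
#' unanimously; the lower bound for k response categories is 1/k of the
#' scorers (0.25 here).  The denominator for each criterion is all scorers
#' who returned a sheet for the matrix — scorers who left a criterion
#' blank are counted in the `"unaware"` category, not excluded.
#'
#' The divisor is the number of criteria actually in the configured set
#' (5 for the default problem set, 2 for the default solution set), so
#' the statistic is always a true mean of its per-criterion fractions.
#'
#' @param matrix a valid [response_matrix()].
#' @param criterion_set the matching [criterion_set()].
#' @return data frame with one row per suggestion: `suggestion_id`,
#'   `aea`, `n_criteria`.  The per-criterion breakdown is attached as
#'   attribute `"per_criterion"` (columns `suggestion_id`, `criterion_id`,
#'   `mode_fraction`, `n_scorers`).
#' @export
aea <- function(matrix, criterion_set) {
  stopifnot(inherits(matrix, "response_matrix"),
            inherits(criterion_set, "criterion_set"))
  if (matrix$kind != criterion_set$kind) {
    abort("kind mismatch between matrix and criterion set")
  }
  cells <- matrix$cells
  crit_ids <- criterion_set$criteria$id
  bad <- setdiff(unique(cells$criterion_id), crit_ids)
  if (length(bad)) {
    abort("criterion id(s) not in the set: ", paste(bad, collapse = ", "))
  }

  sugg <- factor(cells$suggestion_id, levels = matrix$suggestions)
  crit <- factor(cells$criterion_id, levels = crit_ids)
  code <- factor(as_response_code(cells$response), levels = response_codes())
  counts <- table(crit, sugg, code)          # criterion x suggestion x code
  n_scorers <- apply(counts, c(1, 2), sum)   # responses per cell (incl. unaware)
  if (any(n_scorers == 0)) {
    empty <- which(n_scorers == 0, arr.ind = TRUE)
    abort(sprintf(
      "criterion '%s' of suggestion '%s' has no scorers",
      crit_ids[empty[1, 1]], matrix$suggestions[empty[1, 2]]
    ))
  }
  modal <- apply(counts, c(1, 2), max)
  frac <- modal / n_scorers

  per_criterion <- data.frame(
    suggestion_id = rep(matrix$suggestions, each = length(crit_ids)),
    criterion_id = rep(crit_ids, times = length(matrix$suggestions)),
    mode_fraction = as.numeric(frac),
    n_scorers = as.integer(n_scorers),
    stringsAsFactors = FALSE
  )
  out <- data.frame(
    suggestion_id = matrix$suggestions,
    aea = as.numeric(colMeans(frac)),
    n_criteria = length(crit_ids),
    stringsAsFactors = FALSE
  )
  attr(out, "per_criterion") <- per_criterion
  out
}
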