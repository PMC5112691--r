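#' Intermediate score for one (suggestion, criterion) cell
#'
#' The intermediate score is the sum of the numeric response values
#' (yes = 1, no = 0, unsure = 0.5) divided by the number of received
#' (non-unaware) answers, scaled to 0-100.  Unaware responses never enter
#' the numerator or the denominator; with no received answers the score
#' is undefined (`NA`).
#'
#' @param responses character vector of response codes for one cell, one
#'   per enrolled scorer; must be non-empty.
#' @return list with `value` (0-100 or `NA`), `n_received` and
#'   `n_scorers`.
#' @examples
#' intermediate_score(c("yes", "unsure", "unaware"))  # value 75, n_received 2
#' @export
intermediate_score <- function(responses) {
  if (length(responses) == 0) abort("no scorers: `responses` must be non-empty")
  v <- response_value(responses)
  n_received <- sum(!is.na(v))
  value <- if (n_received > 0) 100 * sum(v, na.rm = TRUE) / n_received else NA_real_
  list(value = value, n_received = n_received, n_scorers = length(responses))
}

#' Intermediate scores for every cell of a matrix
#'
#' @param matrix a valid [response_matrix()].
#' @param criterion_set the matching [criterion_set()]; fixes criterion
#'   order in the output.
#' @return data frame with one row per (suggestion, criterion):
#'   `suggestion_id`, `criterion_id`, `value`, `n_received`, `n_scorers`.
#' @export
intermediate_scores <- function(matrix, criterion_set) {
  stopifnot(inherits(matrix, "response_matrix"),
            inherits(criterion_set, "criterion_set"))
  if (matrix$kind != criterion_set$kind) {
    abort("kind mismatch between matrix and criterion set")
  }
  cells <- matrix$cells
  crit_ids <- criterion_set$criteria$id
  sugg <- factor(cells$suggestion_id, levels = matrix$suggestions)
  crit <- factor(cells$criterion_id, levels = crit_ids)
  v <- response_value(cells$response)
  received <- !is.na(v)
  grp <- interaction(crit, sugg, drop = FALSE, lex.order = FALSE)

  sums <- tapply(ifelse(received, v, 0), grp, sum, default = 0)
  n_rec <- tapply(received, grp, sum, default = 0L)
  n_tot <- tapply(rep(1L, nrow(cells)), grp, sum, default = 0L)

  out <- expand.grid(criterion_id = crit_ids, suggestion_id = matrix$suggestions,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n_received <- as.integer(n_rec)
  out$n_scorers <- as.integer(n_tot)
  out$value <- ifelse(out$n_received > 0, 100 * as.numeric(sums) / out$n_received,
                      NA_real_)
  out[, c("suggestion_id", "criterion_id", "value", "n_received", "n_scorers")]
}

#' Composite priority score
#'
#' The priority score of a suggestion is the arithmetic mean of its
#' defined per-criterion intermediate scores.  Criteria where no answer
#' was received (all scorers unaware) are undefined and excluded from the
#' mean; a suggestion with no defined criterion at all has no priority
#' score.
#'
#' @param values numeric vector of intermediate scores (0-100), `NA` for
#'   undefined criteria.
#' @return list with `value` (0-100) and `n_criteria_used`.
#' @examples
#' priority_score(c(80, 60, 70, 90, 100))   # 80
#' priority_score(c(90, NA))                # 90, one criterion used
#' @export
priority_score <- function(values) {
  if (length(values) == 0) abort("`values` must be non-empty")
  defined <- !is.na(values)
  if (!any(defined)) {
    abort("all intermediate scores undefined: no received answers on any criterion")
  }
  list(value = mean(values[defined]), n_criteria_used = sum(defined))
}

#' Score and rank a response matrix
#'
#' Computes per-criterion intermediate scores, composite priority scores
#' and AEA for every suggestion, then ranks suggestions by priority score
#' (descending).  Ties are broken by AEA (descending), then by catalogue
#' order (or first appearance in the matrix when no catalogue is given),
#' so that re-runs are deterministic; tied rows keep distinct consecutive
#' ranks.
#'
#' Suggestions whose every criterion is undefined (no received answers at
#' all) cannot be ranked: by default they are dropped with a warning; with
#' `strict = TRUE` they abort the run.
#'
#' @param matrix a [response_matrix()].
#' @param criterion_set the matching [criterion_set()].
#' @param catalogue optional suggestion catalogue (see
#'   [read_catalogue()]); when supplied, `text`, `kind`,
#'   `breakdown_point` and `factor` columns are attached and catalogue
#'   row order is the final tie-break.
#' @param strict abort instead of warning on unrankable suggestions.
#' @return a `score_table` data frame: `rank`, `suggestion_id`, optional
#'   catalogue columns, one column per criterion id, `n_criteria_used`,
#'   `priority_score`, `aea`.  Scores are kept at full precision; rounding
#'   happens only in [render_report()] / [write_ranked_table()].
#' @export
rank_table <- function(matrix, criterion_set, catalogue = NULL, strict = FALSE) {
  violations <- validate_matrix(matrix, criterion_set)
  if (nrow(violations) > 0) {
    abort(sprintf(
      "invalid response matrix: %d violation(s), e.g. %s; run validate_matrix() for the full report",
      nrow(violations), violations$message[1]
    ))
  }
  crit_ids <- criterion_set$criteria$id
  ints <- intermediate_scores(matrix, criterion_set)

  wide <- matrix(NA_real_, nrow = length(matrix$suggestions),
                 ncol = length(crit_ids),
                 dimnames = list(matrix$suggestions, crit_ids))
  wide[cbind(ints$suggestion_id, ints$criterion_id)] <- ints$value

  defined <- !is.na(wide)
  n_used <- rowSums(defined)
  unrankable <- rownames(wide)[n_used == 0]
  if (length(unrankable)) {
    msg <- paste0("suggestion(s) with no received answers on any criterion ",
                  "excluded from ranking: ",
                  paste(unrankable, collapse = ", "))
    if (strict) abort(msg)
    warning(msg, call. = FALSE)
  }
  keep <- n_used > 0
  pscore <- rowMeans(wide, na.rm = TRUE)

  agreement <- aea(matrix, criterion_set)
  aea_val <- agreement$aea[match(rownames(wide), agreement$suggestion_id)]

  ids <- rownames(wide)
  if (!is.null(catalogue)) {
    catalogue <- validate_catalogue(catalogue)
    unknown <- setdiff(ids, catalogue$id)
    if (length(unknown)) {
      abort("suggestion id(s) absent from catalogue: ",
            paste(unknown, collapse = ", "))
    }
    tie_order <- match(ids, catalogue$id)
  } else {
    tie_order <- seq_along(ids)
  }

  out <- data.frame(
    suggestion_id = ids,
    stringsAsFactors = FALSE
  )
  if (!is.null(catalogue)) {
    m <- match(ids, catalogue$id)
    out$text <- catalogue$text[m]
    out$kind <- catalogue$kind[m]
    out$breakdown_point <- catalogue$breakdown_point[m]
    out$factor <- catalogue$factor[m]
  }
  out <- cbind(out, as.data.frame(wide, stringsAsFactors = FALSE))
  out$n_criteria_used <- as.integer(n_used)
  out$priority_score <- pscore
  out$aea <- aea_val

  out <- out[keep, , drop = FALSE]
  ord <- order(-out$priority_score, -out$aea, tie_order[keep])
  out <- out[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  structure(out, criteria = crit_ids, kind = matrix$kind,
            class = c("score_table", "data.frame"))
}
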