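#' Construct a response matrix
#'
#' A response matrix holds the complete scorer x suggestion x criterion
#' grid of four-valued responses for one suggestion kind.  Blanks on the
#' source sheet are stored as the explicit `"unaware"` code at ingestion,
#' never as an absent cell, so every (scorer, suggestion, criterion)
#' triple is present in a valid matrix.  Problems and solutions are kept
#' in separate matrices because they are scored against different
#' criterion sets.
#'
#' @param cells long-form data frame with columns `scorer_id`,
#'   `suggestion_id`, `criterion_id`, `response`.
#' @param kind `"problem"` or `"solution"`.
#' @param scorers,suggestions,criteria optional orderings/universes of
#'   ids; defaults to first appearance in `cells`.  Supplying them lets
#'   [validate_matrix()] detect cells missing from the source file.
#' @param check if `TRUE` (default) response tokens are normalised with
#'   [as_response_code()] and unknown tokens are an error; with `FALSE`
#'   tokens are kept verbatim so that [validate_matrix()] can report them.
#' @return an object of class `response_matrix`.
#' @seealso [validate_matrix()], [read_scoring_sheets()]
#' @export
response_matrix <- function(cells, kind, scorers = NULL, suggestions = NULL,
                            criteria = NULL, check = TRUE) {
  kind <- match.arg(kind, c("problem", "solution"))
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  required <- c("scorer_id", "suggestion_id", "criterion_id", "response")
  missing <- setdiff(required, names(cells))
  if (length(missing)) {
    abort("cells are missing column(s): ", paste(missing, collapse = ", "))
  }
  cells <- cells[, required]
  for (col in required) cells[[col]] <- as.character(cells[[col]])
  if (check) {
    cells$response <- as_response_code(cells$response)
  } else {
    # still normalise blanks so "blank" and "unaware" are one code
    norm <- trimws(tolower(cells$response))
    norm[is.na(norm) | norm == ""] <- "unaware"
    cells$response <- norm
  }
  structure(
    list(
      cells = cells,
      kind = kind,
      scorers = scorers %||% unique(cells$scorer_id),
      suggestions = suggestions %||% unique(cells$suggestion_id),
      criteria = criteria %||% unique(cells$criterion_id)
    ),
    class = "response_matrix"
  )
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf(
    "<response_matrix> kind: %s | %d scorers x %d suggestions x %d criteria (%d cells)\n",
    x$kind, length(x$scorers), length(x$suggestions), length(x$criteria),
    nrow(x$cells)
  ))
  tab <- table(factor(x$cells$response, levels = response_codes()))
  cat("  responses:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.response_matrix <- function(x, ...) x$cells

empty_violations <- function() {
  data.frame(
    violation = character(), scorer_id = character(),
    suggestion_id = character(), criterion_id = character(),
    message = character(), stringsAsFactors = FALSE
  )
}

violation_rows <- function(violation, scorer_id, suggestion_id, criterion_id,
                           message) {
  data.frame(
    violation = violation, scorer_id = scorer_id,
    suggestion_id = suggestion_id, criterion_id = criterion_id,
    message = message, stringsAsFactors = FALSE
  )
}

#' Validate a response matrix against a criterion set
#'
#' Checks the structural invariants a matrix must satisfy before scoring:
#' every (scorer, suggestion, criterion-of-the-set) triple present exactly
#' once, all response codes known, no criterion ids outside the set.  The
#' check is side-effect free and idempotent.
#'
#' @param matrix a [response_matrix()].
#' @param criterion_set a [criterion_set()] of the same kind; a kind
#'   mismatch is a hard error, not a reported violation.
#' @return a data frame of violations with columns `violation`
#'   (`missing_cell`, `duplicate_cell`, `unknown_code`,
#'   `unknown_criterion`), `scorer_id`, `suggestion_id`, `criterion_id`
#'   and `message`; zero rows if and only if the matrix is valid.
#' @export
validate_matrix <- function(matrix, criterion_set) {
  stopifnot(inherits(matrix, "response_matrix"),
            inherits(criterion_set, "criterion_set"))
  if (matrix$kind != criterion_set$kind) {
    abort(sprintf("kind mismatch: matrix holds %ss but criterion set scores %ss",
                  matrix$kind, criterion_set$kind))
  }
  cells <- matrix$cells
  crit_ids <- criterion_set$criteria$id
  out <- list(empty_violations())

  bad_code <- !(cells$response %in% response_codes())
  if (any(bad_code)) {
    b <- cells[bad_code, ]
    out[[length(out) + 1L]] <- violation_rows(
      "unknown_code", b$scorer_id, b$suggestion_id, b$criterion_id,
      sprintf("unknown response code '%s'", b$response)
    )
  }

  bad_crit <- !(cells$criterion_id %in% crit_ids)
  if (any(bad_crit)) {
    b <- unique(cells[bad_crit, c("scorer_id", "suggestion_id", "criterion_id")])
    out[[length(out) + 1L]] <- violation_rows(
      "unknown_criterion", b$scorer_id, b$suggestion_id, b$criterion_id,
      sprintf("criterion '%s' is not in the %s set", b$criterion_id,
              criterion_set$kind)
    )
  }

  key <- paste(cells$scorer_id, cells$suggestion_id, cells$criterion_id,
               sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    b <- unique(cells[dup, c("scorer_id", "suggestion_id", "criterion_id")])
    out[[length(out) + 1L]] <- violation_rows(
      "duplicate_cell", b$scorer_id, b$suggestion_id, b$criterion_id,
      "more than one response for this (scorer, suggestion, criterion)"
    )
  }

  grid <- expand.grid(
    scorer_id = matrix$scorers, suggestion_id = matrix$suggestions,
    criterion_id = crit_ids,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid_key <- paste(grid$scorer_id, grid$suggestion_id, grid$criterion_id,
                    sep = "\r")
  absent <- !(grid_key %in% key)
  if (any(absent)) {
    b <- grid[absent, ]
    out[[length(out) + 1L]] <- violation_rows(
      "missing_cell", b$scorer_id, b$suggestion_id, b$criterion_id,
      "no cell for this (scorer, suggestion, criterion)"
    )
  }

  do.call(rbind, out)
}
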