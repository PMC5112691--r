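#' Define a criterion set
#'
#' A criterion set is the ordered list of criteria against which every
#' suggestion of one kind is scored.  Problems and solutions are scored
#' against different sets; by default five criteria for problems and two
#' for solutions (see [default_criteria()]).  Order is significant: it
#' fixes the column order of reports.
#'
#' @param kind `"problem"` or `"solution"`.
#' @param criteria data frame with columns `id` (unique short tokens) and
#'   `statement` (the question put to scorers).
#' @return an object of class `criterion_set`.
#' @examples
#' criterion_set("solution", data.frame(
#'   id = c("feasibility", "cost_effectiveness"),
#'   statement = c("Implementation is feasible", "The solution is cost-effective")
#' ))
#' @export
criterion_set <- function(kind, criteria) {
  kind <- match.arg(kind, c("problem", "solution"))
  criteria <- as.data.frame(criteria, stringsAsFactors = FALSE)
  if (!all(c("id", "statement") %in% names(criteria))) {
    abort("`criteria` must have columns 'id' and 'statement'")
  }
  criteria$id <- as.character(criteria$id)
  criteria$statement <- as.character(criteria$statement)
  if (nrow(criteria) == 0) abort("a criterion set must contain at least one criterion")
  if (anyDuplicated(criteria$id)) {
    abort("duplicate criterion id(s): ",
          paste(unique(criteria$id[duplicated(criteria$id)]), collapse = ", "))
  }
  structure(
    list(kind = kind, criteria = criteria[, c("id", "statement")]),
    class = "criterion_set"
  )
}

#' Default criterion sets
#'
#' Problems are judged on five criteria (frequency, severity, inequity,
#' economic impact, responsiveness to solution); solutions on two
#' (feasibility, cost-effectiveness).
#'
#' @param kind `"problem"` or `"solution"`.
#' @return a [criterion_set()].
#' @export
default_criteria <- function(kind = c("problem", "solution")) {
  kind <- match.arg(kind)
  criteria <- if (kind == "problem") {
    data.frame(
      id = c("frequency", "severity", "inequity", "economic_impact",
             "responsiveness"),
      statement = c(
        "The problem occurs frequently in routine care",
        "The problem leads to high rates of death, illness or incapacity",
        "The problem affects disadvantaged groups disproportionately",
        "The problem imposes substantial costs on the healthcare system",
        "The problem is amenable to a solution within five years"
      ),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      id = c("feasibility", "cost_effectiveness"),
      statement = c(
        "Implementation of the solution is feasible",
        "The solution is cost-effective"
      ),
      stringsAsFactors = FALSE
    )
  }
  criterion_set(kind, criteria)
}

#' @export
print.criterion_set <- function(x, ...) {
  cat(sprintf("<criterion_set> kind: %s, %d criteria\n", x$kind, nrow(x$criteria)))
  for (i in seq_len(nrow(x$criteria))) {
    cat(sprintf("  %d. %s: %s\n", i, x$criteria$id[i], x$criteria$statement[i]))
  }
  invisible(x)
}

#' @export
length.criterion_set <- function(x) nrow(x$criteria)

#' Read / write a criterion set as JSON
#'
#' The on-disk form is
#' `{"kind": "problem", "criteria": [{"id": "...", "statement": "..."}]}`.
#'
#' @param path file path.
#' @return `read_criteria()` returns a [criterion_set()];
#'   `write_criteria()` returns `path` invisibly.
#' @export
read_criteria <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(obj$kind) || is.null(obj$criteria)) {
    abort("criterion-set JSON must have fields 'kind' and 'criteria'")
  }
  criterion_set(obj$kind, obj$criteria)
}

#' @param set a [criterion_set()].
#' @rdname read_criteria
#' @export
write_criteria <- function(set, path) {
  stopifnot(inherits(set, "criterion_set"))
  jsonlite::write_json(
    list(kind = set$kind, criteria = set$criteria),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
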