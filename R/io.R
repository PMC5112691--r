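#' Read scoring sheets from a long-form CSV
#'
#' The scoring-sheet dialect is one row per (scorer, suggestion,
#' criterion) with columns `scorer_id,suggestion_id,criterion_id,response`
#' and response tokens `yes`, `no`, `unsure` or the empty string (a blank
#' cell, stored as `"unaware"`).  Unknown response tokens, duplicated
#' triples, and — when a catalogue or criterion set is supplied — unknown
#' suggestion or criterion ids are errors naming the offending line.
#'
#' @param path CSV file path.
#' @param kind `"problem"` or `"solution"`.
#' @param criterion_set optional [criterion_set()]; enables criterion-id
#'   checking and fixes criterion order.
#' @param catalogue optional catalogue data frame; enables suggestion-id
#'   checking and fixes suggestion order.
#' @return a [response_matrix()].
#' @export
read_scoring_sheets <- function(path, kind, criterion_set = NULL,
                                catalogue = NULL) {
  kind <- match.arg(kind, c("problem", "solution"))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = character(),
                         encoding = "UTF-8")
  required <- c("scorer_id", "suggestion_id", "criterion_id", "response")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(sprintf("%s: missing column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  # data line i of the CSV is file line i + 1 (header)
  line <- seq_len(nrow(raw)) + 1L

  norm <- trimws(tolower(raw$response))
  norm[norm == ""] <- "unaware"
  bad <- !(norm %in% response_codes())
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf("%s: line %d: unknown response token '%s'",
                  path, line[i], raw$response[i]))
  }
  raw$response <- norm

  key <- paste(raw$scorer_id, raw$suggestion_id, raw$criterion_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    i <- which(dup)[1]
    abort(sprintf(
      "%s: line %d: duplicate row for scorer '%s', suggestion '%s', criterion '%s'",
      path, line[i], raw$scorer_id[i], raw$suggestion_id[i], raw$criterion_id[i]
    ))
  }

  if (!is.null(criterion_set)) {
    stopifnot(inherits(criterion_set, "criterion_set"))
    if (criterion_set$kind != kind) {
      abort("criterion set kind does not match `kind`")
    }
    bad <- !(raw$criterion_id %in% criterion_set$criteria$id)
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf("%s: line %d: unknown criterion id '%s'",
                    path, line[i], raw$criterion_id[i]))
    }
  }
  suggestions <- NULL
  if (!is.null(catalogue)) {
    catalogue <- validate_catalogue(catalogue)
    cat_ids <- catalogue$id[catalogue$kind == kind]
    bad <- !(raw$suggestion_id %in% cat_ids)
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf("%s: line %d: unknown suggestion id '%s'",
                    path, line[i], raw$suggestion_id[i]))
    }
    suggestions <- cat_ids[cat_ids %in% raw$suggestion_id]
  }

  response_matrix(
    raw, kind,
    suggestions = suggestions,
    criteria = if (!is.null(criterion_set)) criterion_set$criteria$id
  )
}

#' Write scoring sheets to the long-form CSV dialect
#'
#' Inverse of [read_scoring_sheets()]: `"unaware"` cells are written as
#' the empty string (a blank on the sheet), so a write/read round trip
#' reproduces the matrix cells exactly.
#'
#' @param matrix a [response_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scoring_sheets <- function(matrix, path) {
  stopifnot(inherits(matrix, "response_matrix"))
  out <- matrix$cells
  out$response[out$response == "unaware"] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# Rounded presentation copy of a score table (full precision is kept in
# the score_table itself).
format_score_table <- function(table, top_n = nrow(table), score_digits = 1,
                               aea_digits = 4) {
  stopifnot(inherits(table, "score_table"))
  if (top_n < 1) abort("`top_n` must be at least 1")
  top_n <- min(top_n, nrow(table))
  out <- as.data.frame(table)[seq_len(top_n), , drop = FALSE]
  crit <- attr(table, "criteria")
  for (col in c(crit, "priority_score")) {
    out[[col]] <- round_half_up(out[[col]], score_digits)
  }
  out$aea <- round_half_up(out$aea, aea_digits)
  out
}

#' Render a ranked report
#'
#' Formats the top rows of a score table in rank order with per-criterion
#' scores, the priority score (1 decimal, half away from zero, matching
#' published presentation) and AEA (4 decimals), as either aligned text or
#' CSV lines.  Both renderings carry identical values and re-rendering the
#' same table is byte-identical.
#'
#' @param table a `score_table` from [rank_table()].
#' @param top_n number of leading rows to include (default 10).
#' @param format `"text"` or `"csv"`.
#' @param score_digits,aea_digits decimals for scores and AEA.
#' @return character vector of report lines.
#' @export
render_report <- function(table, top_n = 10, format = c("text", "csv"),
                          score_digits = 1, aea_digits = 4) {
  format <- match.arg(format)
  out <- format_score_table(table, top_n, score_digits, aea_digits)
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "rank" &
    names(out) != "n_criteria_used"
  for (col in names(out)[num]) {
    digits <- if (col == "aea") aea_digits else score_digits
    out[[col]] <- formatC(out[[col]], format = "f", digits = digits)
  }
  if (format == "csv") {
    con <- textConnection("lines", "w", local = TRUE)
    utils::write.csv(out, con, row.names = FALSE, quote = TRUE)
    close(con)
    return(lines)
  }
  header <- toupper(names(out))
  widths <- pmax(nchar(header),
                 vapply(out, function(x) max(nchar(as.character(x)), 0L),
                        integer(1)))
  pad <- function(x, w) formatC(as.character(x), width = w)
  lines <- paste(mapply(pad, header, widths), collapse = "  ")
  for (i in seq_len(nrow(out))) {
    lines <- c(lines, paste(mapply(pad, unlist(out[i, ]), widths),
                            collapse = "  "))
  }
  lines
}

#' Write / read a ranked table CSV
#'
#' `write_ranked_table()` writes the presentation form of a score table
#' (scores rounded to `score_digits`, AEA to `aea_digits`);
#' `read_ranked_table()` reads it back as a plain data frame.
#'
#' @param table a `score_table` from [rank_table()].
#' @param path CSV path.
#' @inheritParams render_report
#' @return `write_ranked_table()` returns `path` invisibly;
#'   `read_ranked_table()` returns a data frame.
#' @export
write_ranked_table <- function(table, path, score_digits = 1, aea_digits = 4) {
  out <- format_score_table(table, nrow(table), score_digits, aea_digits)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_ranked_table
#' @export
read_ranked_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}

#' Write all artifacts of a synthetic cohort
#'
#' Writes `problems_sheets.csv`, `solutions_sheets.csv`, `catalogue.csv`
#' and `truth.csv` into a directory, the same layout the command-line
#' `simulate` subcommand produces.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_scoring_sheets(cohort$problems, file.path(dir, "problems_sheets.csv"))
  write_scoring_sheets(cohort$solutions, file.path(dir, "solutions_sheets.csv"))
  write_catalogue(cohort$catalogue, file.path(dir, "catalogue.csv"))
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(dir)
}
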