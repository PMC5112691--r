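#' Category vocabularies for the suggestion catalogue
#'
#' Each collated suggestion carries two human-assigned category labels:
#' the stage of the medication process where the breakdown occurs, and a
#' London Protocol-derived factor category (for problems a contributory
#' factor, for solutions the type of solution).  Both vocabularies are
#' closed by default but can be extended when reading a catalogue, since
#' full collated lists may use labels beyond those in published top-ten
#' tables.
#'
#' @return character vector of canonical labels.
#' @export
breakdown_points <- function() {
  c("prescribing", "dispensing", "administering", "monitoring",
    "transfer_of_care", "communication_with_patient_carers")
}

#' @rdname breakdown_points
#' @export
factor_categories <- function() {
  c("individual_staff", "patient", "work_environment", "task_design")
}

#' Validate a suggestion catalogue
#'
#' A catalogue is a data frame with one row per collated suggestion and
#' columns `id`, `text`, `kind` (`problem`/`solution`), `breakdown_point`
#' and `factor`.  Category labels are inputs assigned by human coders,
#' never computed here.
#'
#' @param catalogue data frame as above.
#' @param extra_breakdown_points,extra_factors additional admissible
#'   labels beyond the defaults.
#' @return the validated catalogue (invisibly unchanged), with character
#'   columns.
#' @export
validate_catalogue <- function(catalogue,
                               extra_breakdown_points = character(),
                               extra_factors = character()) {
  catalogue <- as.data.frame(catalogue, stringsAsFactors = FALSE)
  required <- c("id", "text", "kind", "breakdown_point", "factor")
  missing <- setdiff(required, names(catalogue))
  if (length(missing)) {
    abort("catalogue is missing column(s): ", paste(missing, collapse = ", "))
  }
  for (col in required) catalogue[[col]] <- as.character(catalogue[[col]])
  if (anyDuplicated(catalogue$id)) {
    abort("duplicate suggestion id(s): ",
          paste(unique(catalogue$id[duplicated(catalogue$id)]), collapse = ", "))
  }
  bad_kind <- setdiff(unique(catalogue$kind), c("problem", "solution"))
  if (length(bad_kind)) {
    abort("unknown suggestion kind(s): ", paste(sQuote(bad_kind), collapse = ", "))
  }
  bp_ok <- c(breakdown_points(), extra_breakdown_points)
  bad_bp <- setdiff(unique(catalogue$breakdown_point), bp_ok)
  if (length(bad_bp)) {
    abort("unknown breakdown point(s): ", paste(sQuote(bad_bp), collapse = ", "))
  }
  f_ok <- c(factor_categories(), extra_factors)
  bad_f <- setdiff(unique(catalogue$factor), f_ok)
  if (length(bad_f)) {
    abort("unknown factor categor(ies): ", paste(sQuote(bad_f), collapse = ", "))
  }
  invisible(catalogue)
}

#' Read / write a suggestion catalogue CSV
#'
#' Columns `id,text,kind,breakdown_point,factor`, UTF-8, header required.
#'
#' @param path file path.
#' @inheritParams validate_catalogue
#' @return `read_catalogue()` returns the validated catalogue data frame;
#'   `write_catalogue()` returns `path` invisibly.
#' @export
read_catalogue <- function(path,
                           extra_breakdown_points = character(),
                           extra_factors = character()) {
  catalogue <- utils::read.csv(path, stringsAsFactors = FALSE,
                               colClasses = "character", encoding = "UTF-8")
  validate_catalogue(catalogue,
                     extra_breakdown_points = extra_breakdown_points,
                     extra_factors = extra_factors)
  catalogue
}

#' @param catalogue a catalogue data frame.
#' @rdname read_catalogue
#' @export
write_catalogue <- function(catalogue, path) {
  validate_catalogue(catalogue)
  utils::write.csv(catalogue, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
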