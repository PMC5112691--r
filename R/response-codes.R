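#' The four response codes
#'
#' Scorers answer every (suggestion, criterion) question with one of four
#' options: `"yes"` (numeric value 1), `"no"` (0), `"unsure"` (0.5) or
#' `"unaware"` (left blank on the sheet; carries no numeric value and is
#' excluded from score denominators, but counts as a valid response
#' category when measuring agreement).
#'
#' @return `response_codes()` returns the four code tokens in canonical
#'   order.  `response_value()` returns the numeric score contribution of
#'   each code (`NA` for `"unaware"`).
#' @examples
#' response_codes()
#' response_value(c("yes", "unsure", "unaware"))
#' @export
response_codes <- function() {
  c("yes", "no", "unsure", "unaware")
}

.response_values <- c(yes = 1, no = 0, unsure = 0.5, unaware = NA_real_)

#' @param code character vector of response codes.
#' @rdname response_codes
#' @export
response_value <- function(code) {
  code <- as_response_code(code)
  unname(.response_values[code])
}

#' Normalise raw response tokens
#'
#' Trims whitespace, lowercases, and maps the empty string (a blank cell
#' on a scoring sheet) to `"unaware"`.  Any other token is rejected.
#'
#' @param x character vector of raw tokens.
#' @return character vector of canonical response codes.
#' @export
as_response_code <- function(x) {
  x <- trimws(tolower(as.character(x)))
  x[is.na(x) | x == ""] <- "unaware"
  bad <- setdiff(unique(x), response_codes())
  if (length(bad)) {
    abort("unknown response code(s): ", paste(sQuote(bad), collapse = ", "))
  }
  x
}
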