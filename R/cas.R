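#' Validate a CAS Registry Number
#'
#' A CAS-RN has the form `NNNNNNN-NN-R`: a body of 2-7 digits, a two-digit
#' segment, and a single check digit `R`. The check digit is the weighted sum
#' of the other digits (weights 1, 2, 3, ... counted from the digit
#' immediately left of the check digit) modulo 10. Registries in this package
#' key substances on CAS-RN, so malformed or mistyped identifiers are caught
#' at registration time.
#'
#' @param cas character vector of candidate CAS numbers.
#' @return character vector with one verdict per input:
#'   `"valid"`, `"malformed"` (pattern violation) or `"checksum_fail"`
#'   (well-formed but the check digit does not match).
#' @examples
#' validate_cas(c("107-36-8", "ABC-12-3", "107-36-9"))
#' @export
validate_cas <- function(cas) {
  vapply(as.character(cas), function(x) {
    if (is.na(x) || !grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", x)) {
      return("malformed")
    }
    digits <- as.integer(strsplit(gsub("-", "", x), "")[[1]])
    n <- length(digits)
    check <- digits[n]
    body <- digits[-n]
    if (cas_check_digit(body) == check) "valid" else "checksum_fail"
  }, character(1), USE.NAMES = FALSE)
}

# check digit for a vector of body digits (most significant first)
cas_check_digit <- function(body) {
  weights <- rev(seq_along(body))
  sum(weights * body) %% 10L
}

#' Generate a syntactically valid CAS-like identifier
#'
#' Used by the fixture generators: draws a random numeric body and appends
#' the correct check digit, so every generated identifier passes
#' [validate_cas()]. Not guaranteed to correspond to a real substance.
#'
#' @param n number of identifiers.
#' @return character vector of length `n`, all `"valid"` under
#'   [validate_cas()]. Uses the current RNG stream.
#' @export
random_cas <- function(n) {
  vapply(seq_len(n), function(i) {
    body <- c(sample(1:9, 1), sample(0:9, sample(3:8, 1), replace = TRUE))
    nb <- length(body)
    paste0(
      paste(body[1:(nb - 2)], collapse = ""), "-",
      paste(body[(nb - 1):nb], collapse = ""), "-",
      cas_check_digit(body)
    )
  }, character(1))
}
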