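# Internal helpers: classed conditions and SNOMED CT identifier checks.

sct_error <- function(class, message, ..., call = sys.call(-1)) {
  stop(structure(
    class = c(class, "sctfhir_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

#' Validate a SNOMED CT concept identifier
#'
#' A concept identifier is a string of 6 to 18 decimal digits without a
#' leading zero. Real SNOMED CT identifiers additionally carry a Verhoeff
#' check digit as their last digit; synthetic fixture identifiers do not, so
#' check-digit validation is opt-in.
#'
#' @param x Character vector of candidate identifiers.
#' @param check_digit If `TRUE`, also require the final digit to be a valid
#'   Verhoeff checksum over the preceding digits.
#' @return Logical vector, one element per input.
#' @examples
#' is_concept_id(c("71620000", "012345", "12345"))
#' is_concept_id("71620000", check_digit = TRUE)
#' @export
is_concept_id <- function(x, check_digit = FALSE) {
  ok <- grepl("^[1-9][0-9]{5,17}$", x)
  if (check_digit) {
    ok[ok] <- vapply(x[ok], verhoeff_valid, logical(1))
  }
  ok
}

# Verhoeff dihedral-group tables (standard construction).
.verhoeff_d <- matrix(c(
  0,1,2,3,4,5,6,7,8,9,
  1,2,3,4,0,6,7,8,9,5,
  2,3,4,0,1,7,8,9,5,6,
  3,4,0,1,2,8,9,5,6,7,
  4,0,1,2,3,9,5,6,7,8,
  5,9,8,7,6,0,4,3,2,1,
  6,5,9,8,7,1,0,4,3,2,
  7,6,5,9,8,2,1,0,4,3,
  8,7,6,5,9,3,2,1,0,4,
  9,8,7,6,5,4,3,2,1,0), nrow = 10, byrow = TRUE)
.verhoeff_p <- matrix(c(
  0,1,2,3,4,5,6,7,8,9,
  1,5,7,6,2,8,3,0,9,4,
  5,8,0,3,7,9,6,1,4,2,
  8,9,1,6,0,4,3,5,2,7,
  9,4,5,3,1,2,6,8,7,0,
  4,2,8,6,5,7,3,9,0,1,
  2,7,9,3,8,0,6,4,1,5,
  7,0,4,6,9,1,3,2,5,8), nrow = 8, byrow = TRUE)

verhoeff_valid <- function(x) {
  digits <- rev(as.integer(strsplit(x, "")[[1]]))
  c_val <- 0L
  for (i in seq_along(digits)) {
    c_val <- .verhoeff_d[c_val + 1L, .verhoeff_p[((i - 1L) %% 8L) + 1L, digits[i] + 1L] + 1L]
  }
  c_val == 0L
}

#' Compute the Verhoeff check digit for a digit string
#'
#' @param x A string of decimal digits (without the check digit).
#' @return The single check digit as an integer.
#' @keywords internal
verhoeff_digit <- function(x) {
  .verhoeff_inv <- c(0L, 4L, 3L, 2L, 1L, 5L, 6L, 7L, 8L, 9L)
  digits <- rev(as.integer(strsplit(x, "")[[1]]))
  c_val <- 0L
  for (i in seq_along(digits)) {
    c_val <- .verhoeff_d[c_val + 1L, .verhoeff_p[(i %% 8L) + 1L, digits[i] + 1L] + 1L]
  }
  .verhoeff_inv[c_val + 1L]
}

# Numeric-order sort of digit-string identifiers (lengths may exceed double
# precision, so order by length, then lexicographically).
sort_ids <- function(x) {
  if (length(x) == 0) return(character(0))
  x[order(nchar(x), x, method = "radix")]
}

id_lt <- function(a, b) {
  if (nchar(a) != nchar(b)) nchar(a) < nchar(b) else a < b
}
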