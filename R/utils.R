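#' Round half away from zero
#'
#' Commercial rounding used for all reported percentages: ties go away from
#' zero (`round_half_away(0.5) == 1`), unlike [base::round()]'s banker's
#' rounding. Published tables in this field are rounded this way.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return Numeric vector of the same length as `x`.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5), 0)
#' round_half_away(45.5, 0)
round_half_away <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# internal: stop() with a consistent invalid-input prefix
stop_invalid <- function(...) {
  stop(paste0("invalid input: ", ...), call. = FALSE)
}

# internal: check a scalar positive number, naming the offending field
check_positive <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_invalid(sprintf("'%s' must be positive and finite", field))
  }
  invisible(x)
}
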