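# Shared helpers: condition constructors and display rounding.

stop_domain <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("fluorisk_domain_error", "fluorisk_error")))
}

stop_usage <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("fluorisk_usage_error", "fluorisk_error")))
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (so `round_half_up(2.345, 2)`
#' is 2.35), the convention used for all display-rounded values in this
#' package. Base [round()] rounds ties to even, which does not reproduce
#' the published tables.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @export
#' @examples
#' round_half_up(c(0.125, -0.125), 2)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # small epsilon guards against values like 2.3049999999 that are 2.305 in
  # exact arithmetic
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# check a scalar is a finite number, optionally positive / non-negative
check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_domain(sprintf("'%s' must be a single finite number", name))
  }
  if (positive && x <= 0) stop_domain(sprintf("'%s' must be > 0", name))
  if (nonneg && x < 0) stop_domain(sprintf("'%s' must be >= 0", name))
  invisible(x)
}
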