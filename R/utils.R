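#' Round half away from zero
#'
#' Base `round()` rounds half to even; the scoring and interval conventions
#' here need ordinary half-up rounding (7.5 -> 8, 0.85 -> 0.9).
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded vector
#' @keywords internal
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Truncate toward zero at a number of decimals
#' @keywords internal
trunc_decimals <- function(x, digits = 2L) {
  p <- 10^digits
  trunc(x * p) / p
}

# stop() with a classed condition so callers can test on error class
abort <- function(message, class) {
  stop(structure(
    class = c(class, "ohppfwa_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
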