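#' Round half up at a fixed number of decimals
#'
#' Decimal rounding with ties going away from zero, as used when reporting
#' estimates at the precision of the published tables. A small epsilon guards
#' against decimal half-values that binary doubles store just below the tie
#' (e.g. 40.55 stored as 40.549999...), so they still round up as printed.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return `x` rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(40.55, 1)  # 40.6
#' round_half_up(141.578)   # 142
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Stop with a consistent error class so the CLI can map validation failures
# to a dedicated exit code.
abort_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("crocallometry_validation", "error")))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_positive_scalar <- function(x, name) {
  if (!is_scalar_number(x) || x <= 0) {
    abort_validation(name, " must be a single positive finite number")
  }
  invisible(x)
}
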