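#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published carrier percentages
#' (e.g. "2.3" for 1/44) follow the conventional half-up rule, so tabulated
#' output uses this helper instead.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(2.25, 1) # 2.3
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# format a fraction as a percent string with d decimals, half-up
percent_string <- function(x, digits = 1) {
  formatC(round_half_up(100 * x, digits), format = "f", digits = digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

# scalar checks used by validators
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

is_fraction <- function(x) is_scalar_number(x) && x >= 0 && x <= 1

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_input(sprintf("%s: missing required column(s): %s",
                       what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
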