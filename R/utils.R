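# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; the tabulated cumulative percents
#' follow the conventional half-up rule (e.g. 75.6 -> 76, 19.6 -> 20), so the
#' pipeline uses this explicit variant wherever integer percents are printed.
#'
#' @param x Numeric vector.
#' @return Numeric vector rounded to integers, halves away from zero.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 75.6))
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# stop() with a consistent error class so tests can target pipeline errors
abort_emogate <- function(msg, class = "emogate_error") {
  rlang::abort(msg, class = c(class, "emogate_error"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
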