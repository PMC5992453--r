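#' Half-up decimal rounding
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (\dQuote{half-up}), the convention used in clinical manuscripts. Base R's
#' [round()] uses IEC 60559 round-half-even, which turns 1.265 into 1.26;
#' published tables print 1.27.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(1.265, 2) # 1.27
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Two-stage report rounding
#'
#' Rounds half-up at a working precision first, then at the display
#' precision. Statistical software typically displays three decimals (or
#' percentages at one decimal); manuscripts then round that display to two
#' decimals. A value of 0.7947 displays as 0.795 and is transcribed as 0.80,
#' which single-stage rounding cannot produce. Used for confidence bounds and
#' p values when matching published tables.
#'
#' @param x Numeric vector.
#' @param display Final number of decimals.
#' @param working Intermediate (software display) number of decimals.
#' @return Numeric vector.
#' @export
round_report <- function(x, display = 2, working = 3) {
  round_half_up(round_half_up(x, working), display)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_drs <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "drs_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
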