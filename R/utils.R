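#' @importFrom rlang .data .env
#' @importFrom dplyr %>%
NULL

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (so 0.425 -> 0.43 at two
#' decimals), matching the presentation convention used for all displayed
#' percentages and indicator scores. Base [round()] rounds half to even, which
#' would disagree with printed tables at exact ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_up(0.425, 2)
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Derive a stream of child seeds from one integer seed, staying < 2^31.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
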