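#' Round half away from zero
#'
#' Report-style rounding: 0.05 rounds to 0.1 and -0.05 to -0.1, unlike
#' base \code{round}'s round-half-even. A tiny epsilon guards against
#' binary representation of decimal halves.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
roundHalfAway <- function(x, digits = 1) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage of a count over a total
#'
#' @param count,total non-negative counts, \code{total > 0}.
#' @param digits decimal places (half-away-from-zero rounding).
#' @return percentage.
#' @examples
#' percentOf(17, 18)  # 94.4
#' percentOf(6, 17)   # 35.3
#' @export
percentOf <- function(count, total, digits = 1) {
    if (any(total <= 0)) stop("'total' must be positive")
    roundHalfAway(100 * count / total, digits)
}
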