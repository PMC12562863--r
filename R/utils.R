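#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used when reporting percentages in
#' summary tables. Base R's `round()` rounds half to even, which disagrees
#' with how published QTL summary tables are typically rounded.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(2.5, 0)   # 3, not 2
#' round_half_up(14.285, 1)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Percentage of a count over a total, rounded half-up
#'
#' @param numerator,denominator Counts.
#' @param digits Decimal places for the printed percentage.
#' @return `100 * numerator / denominator`, rounded half-up.
#' @export
pct_of <- function(numerator, denominator, digits = 1) {
  round_half_up(100 * numerator / denominator, digits)
}

# Derive a child seed from a root seed; stays within 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1009 + index * 9973) %% 2147483647)
}

# Weighted quantile of x at probabilities probs (type-4-like, linear in the
# cumulative weight). Used for deterministic EM initialization.
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) {
    i <- findInterval(p, cw) + 1L
    x[min(i, length(x))]
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
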