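# Shared small helpers: amino acid alphabet, rounding/percent conventions,
# the Kolmogorov survival function used by the KS approximation.

#' The 20 canonical one-letter amino acid codes
#'
#' Variant tables are restricted to this alphabet; rows using extended
#' codes (B, Z, X, U, ...) are dropped and counted by the readers.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Percentage of a count, at reporting precision
#'
#' All mapping, contamination and coverage percentages in reports are
#' `100 * k / n` rounded to 2 decimals with round-half-even (the IEC 60559
#' behaviour of [round()]). Returns 0 when `n` is zero so empty datasets
#' report zero rates rather than NaN.
#'
#' @param k Numerator count.
#' @param n Denominator count.
#' @return A number in `[0, 100]` with 2 decimals.
#' @examples
#' percent_of(39081, 446013) # 8.76
#' @export
percent_of <- function(k, n) {
  stopifnot(is.numeric(k), is.numeric(n), k >= 0, n >= 0)
  if (n == 0) return(0)
  round(100 * k / n, 2)
}

# Survival function of the Kolmogorov distribution,
#   Q(lambda) = 2 * sum_{j>=1} (-1)^(j-1) exp(-2 j^2 lambda^2),
# truncated when terms vanish; clamped to [0, 1].
kolmogorov_sf <- function(lambda) {
  if (lambda <= 0) return(1)
  j <- seq_len(101)
  terms <- (-1)^(j - 1) * exp(-2 * j^2 * lambda^2)
  min(1, max(0, 2 * sum(terms)))
}

# stop() with a named offending parameter, used by config validators
stop_param <- function(param, msg) {
  stop(sprintf("invalid `%s`: %s", param, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
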