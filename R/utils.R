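# shared small helpers

# round half away from zero, the convention used in the published tables
# (base::round rounds half to even)
roundHalfUp <- function(x, digits = 0L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Percentage with half-up rounding
#'
#' `100 * numerator / denominator` rounded half-up to `decimals` places —
#' the arithmetic behind every "% of total" column in the output tables.
#'
#' @param numerator,denominator non-negative numbers; `denominator` must be
#'   positive.
#' @param decimals number of decimal places (default 1).
#' @return a single numeric percentage.
#' @examples
#' percentOf(6006, 698670, 1)      # 0.9
#' percentOf(20318, 186526, 2)     # 10.89
#' @export
percentOf <- function(numerator, denominator, decimals = 1L) {
  stopifnot(is.numeric(numerator), is.numeric(denominator),
            length(numerator) == 1L || length(denominator) == 1L ||
              length(numerator) == length(denominator))
  if (any(denominator <= 0))
    stop("percentOf: denominator must be > 0")
  roundHalfUp(100 * numerator / denominator, decimals)
}

# deterministic per-purpose seed derivation, kept under 2^31
# (double arithmetic: exact well past 2^31 * 12347, avoids integer overflow)
deriveSeed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 1103 + as.numeric(salt) * 12347) %%
               2147483587)
}

vlog <- function(stage, ..., verbose = TRUE) {
  if (isTRUE(verbose))
    message(sprintf("[%s] %s", stage, paste0(...)))
  invisible(NULL)
}
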