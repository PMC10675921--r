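# Shared internal helpers.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed report percentages use the
#' conventional half-up rule (e.g. 95.25 -> 95.3 at one decimal).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Percentage with half-up rounding; NA on zero denominator.
pct_of <- function(num, den, digits = 1) {
  if (is.na(den) || den == 0) return(NA_real_)
  round_half_up(100 * num / den, digits)
}

# Reverse complement for plain character vectors.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
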