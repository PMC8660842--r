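#' Round half away from zero
#'
#' Display rounding used in the report tables: 0.875 -> 0.88 at two
#' decimals, unlike base \code{round()}'s round-half-to-even.
#'
#' @param x numeric
#' @param digits decimal places
#' @return rounded numeric
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a stream-specific 32-bit sub-seed from a master seed; keeps every
# source of randomness tied to one user-visible seed.
subSeed <- function(seed, stream) {
  (as.integer(seed) %% 2147480000L + 7919L * as.integer(stream)) %% 2147483647L
}

# Split a semicolon-joined flag field back into a character vector.
splitFlags <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

joinFlags <- function(x) paste(x, collapse = ";")
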