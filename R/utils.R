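`%||%` <- function(a, b) if (is.null(a)) b else a

## round() uses banker's rounding; copy-number states and multiplicities are
## conventionally rounded half-up, so 2.5 -> 3.
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement over plain character vectors (ACGT alphabet).
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Run an expression with a temporary RNG seed
#'
#' All stochastic operations in the package route their randomness through
#' this wrapper so that results are reproducible and the caller's RNG state
#' is left untouched.
#'
#' @keywords internal
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

## Derive a stream-specific child seed from a master seed, staying within
## 32-bit integer range.
child_seed <- function(seed, stream) {
  (as.integer(seed) * 7919L + as.integer(stream) * 104729L) %% 2147483647L
}

stop_mseq <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
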