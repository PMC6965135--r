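#' The 96 trinucleotide substitution categories
#'
#' Single-base substitutions are reported in the pyrimidine frame: a mutated
#' purine is reverse-complemented so that the central reference base is C or
#' T. With 6 substitution types and 4 x 4 flanking bases this yields the
#' standard 96 categories, ordered substitution-major:
#' `A[C>A]A, A[C>A]C, ..., T[T>G]T`.
#'
#' @return character vector of length 96 with labels such as `"A[C>T]G"`.
#' @export
#' @examples
#' head(context96_labels())
context96_labels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  fl <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(fl, fl, function(l, r) paste0(l, "[", s, "]", r))))
  }))
}

PYRIMIDINES <- c("C", "T")
BASES <- c("A", "C", "G", "T")

#' Classify substitutions into the 96 pyrimidine-frame categories
#'
#' @param ref reference base (character vector).
#' @param alt alternate base.
#' @param triplet reference trinucleotide centred on the mutated base
#'   (5' flank, ref, 3' flank).
#' @return character vector of category labels (see [context96_labels()]).
#' @export
#' @examples
#' classify_context96("C", "T", "ACA")  # "A[C>T]A"
#' classify_context96("G", "A", "TGT")  # also "A[C>T]A" (reverse complement)
classify_context96 <- function(ref, alt, triplet) {
  stopifnot(length(ref) == length(alt), length(ref) == length(triplet))
  if (length(ref) == 0L) return(character(0))
  if (any(substr(triplet, 2L, 2L) != ref)) {
    stop_mseq("triplet central base does not match ref allele")
  }
  purine <- !(ref %in% PYRIMIDINES)
  triplet[purine] <- revcomp(triplet[purine])
  alt[purine] <- chartr("ACGT", "TGCA", alt[purine])
  ref[purine] <- substr(triplet[purine], 2L, 2L)
  paste0(
    substr(triplet, 1L, 1L), "[", ref, ">", alt, "]", substr(triplet, 3L, 3L)
  )
}

## All 32 pyrimidine-frame trinucleotides (central base C or T).
trinuc32 <- function() {
  fl <- BASES
  out <- character(0)
  for (mid in PYRIMIDINES) {
    out <- c(out, as.vector(t(outer(fl, fl, function(l, r) paste0(l, mid, r)))))
  }
  out
}

## Alternate alleles available for a pyrimidine-frame context label base.
alt_bases <- function(ref) setdiff(BASES, ref)

## Split a context label "A[C>T]G" into its parts.
parse_context96 <- function(label) {
  data.frame(
    fl5 = substr(label, 1L, 1L),
    ref = substr(label, 3L, 3L),
    alt = substr(label, 5L, 5L),
    fl3 = substr(label, 7L, 7L),
    trinuc = paste0(substr(label, 1L, 1L), substr(label, 3L, 3L),
                    substr(label, 7L, 7L)),
    stringsAsFactors = FALSE
  )
}
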