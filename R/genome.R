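#' Generate a toy reference genome
#'
#' Builds a small multi-chromosome reference of random sequence, used by the
#' tumour simulator and by context counting. Chromosome names are autosome
#' labels ("1", "2", ...) so that downstream copy-number metrics (which are
#' restricted to autosomes) apply directly. Each chromosome is tiled with
#' consecutive in-frame gene intervals so that coding consequences can be
#' derived from actual codon changes.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each chromosome in bp (made divisible by
#'   the gene length).
#' @param gene_length length of each gene tile in bp; must be a multiple of 3.
#' @param seed RNG seed.
#' @return object of class `mseq_genome`: list with `seq` (named character
#'   vector of chromosome sequences), `genes` (data.frame gene/chrom/start/end)
#'   and `gene_length`.
#' @export
toy_genome <- function(n_chrom = 4L, chrom_length = 30000L,
                       gene_length = 1500L, seed = 1L) {
  stopifnot(gene_length %% 3L == 0L, n_chrom >= 1L)
  chrom_length <- as.integer(chrom_length %/% gene_length) * gene_length
  stopifnot(chrom_length >= gene_length)
  chroms <- as.character(seq_len(n_chrom))
  ## chromosomes are built from stop-free codons so that every gene tile is
  ## a valid open reading frame (the toy genome is fully coding)
  code <- Biostrings::GENETIC_CODE
  ok_codons <- names(code)[code != "*"]
  seqs <- with_seed(seed, {
    vapply(chroms, function(ch) {
      paste(sample(ok_codons, chrom_length %/% 3L, replace = TRUE),
            collapse = "")
    }, character(1))
  })
  genes_per_chrom <- chrom_length %/% gene_length
  total_genes <- n_chrom * genes_per_chrom
  gene_names <- gene_symbols(total_genes)
  genes <- data.frame(
    gene = gene_names,
    chrom = rep(chroms, each = genes_per_chrom),
    start = rep(seq(1L, chrom_length, by = gene_length), times = n_chrom),
    stringsAsFactors = FALSE
  )
  genes$end <- genes$start + gene_length - 1L
  structure(
    list(seq = seqs, genes = genes, gene_length = gene_length),
    class = "mseq_genome"
  )
}

## Gene names: recurrent dMMR gastro-oesophageal driver genes first (so the
## driver catalog maps onto real loci), generic symbols after.
DRIVER_GENES <- c(
  "TP53", "KRAS", "NRAS", "PIK3CA", "B2M", "ARID1A", "ARID1B", "ARID2",
  "SMARCA4", "MLH1", "MSH6", "RNF43", "APC", "ACVR2A", "PRDM2", "JAK1",
  "JAK2", "PBRM1", "CHEK2", "ATR", "BLM", "PTEN"
)

gene_symbols <- function(n) {
  extras <- sprintf("GENE%03d", seq_len(max(0L, n - length(DRIVER_GENES))))
  c(DRIVER_GENES, extras)[seq_len(n)]
}

#' Example driver-gene catalog
#'
#' A small catalog of genes recurrently altered in mismatch-repair-deficient
#' gastro-oesophageal cancers, with their oncogene/tumour-suppressor role,
#' known protein changes and known mutated positions. Used by
#' [classify_driver()]. Entries are curated for the toy analyses shipped with
#' the package, not a clinical resource.
#'
#' @return data.frame with columns `gene`, `role` (`oncogene`/`tsg`),
#'   `known_changes` (comma-separated protein changes) and `known_positions`
#'   (comma-separated residue numbers).
#' @export
driver_catalog <- function() {
  df <- utils::read.delim(
    system.file("extdata", "driver_catalog.tsv", package = "mseqevo"),
    stringsAsFactors = FALSE, colClasses = "character", fill = TRUE
  )
  for (cn in c("known_changes", "known_positions")) {
    if (is.null(df[[cn]])) df[[cn]] <- ""
    df[[cn]][is.na(df[[cn]])] <- ""
  }
  df
}

#' Synthetic 96-context signature catalog
#'
#' Generates a deterministic catalog shaped like the classical 30-signature
#' substitution catalogs (96 contexts x `n_sig` columns, each column a
#' probability vector). Signatures are sparse random profiles with a few
#' dominant peaks, which makes them linearly independent and suitable for
#' refitting tests and simulations. This is a synthetic stand-in, not the
#' published reference catalog.
#'
#' @param n_sig number of signature columns.
#' @param seed RNG seed (fixed default so the catalog is stable).
#' @param peak_weight total probability mass concentrated on the peaks.
#' @return 96 x `n_sig` numeric matrix; rownames are context labels, colnames
#'   `S1..Sn`.
#' @export
synthetic_signature_catalog <- function(n_sig = 30L, seed = 20260101L,
                                        peak_weight = 0.6) {
  labels <- context96_labels()
  with_seed(seed, {
    mat <- matrix(0, nrow = 96L, ncol = n_sig,
                  dimnames = list(labels, paste0("S", seq_len(n_sig))))
    for (j in seq_len(n_sig)) {
      base <- stats::rgamma(96L, shape = 0.15)
      base <- base / sum(base)
      peaks <- sample.int(96L, 4L)
      pk <- stats::rgamma(4L, shape = 1)
      pk <- pk / sum(pk) * peak_weight
      col <- base * (1 - peak_weight)
      col[peaks] <- col[peaks] + pk
      mat[, j] <- col / sum(col)
    }
    mat
  })
}

#' Write a genome to FASTA
#'
#' @param genome an `mseq_genome`.
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$seq), path)
  invisible(path)
}

#' Read a FASTA reference into the sequence container used by the package
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

## Index genome positions (excluding contig edges) by their pyrimidine-frame
## trinucleotide. Returns a list mapping trinucleotide -> data.frame(chrom,
## pos, strandflip) where strandflip marks positions whose reference base is
## a purine (context taken from the reverse complement).
context_position_index <- function(genome) {
  idx <- list()
  for (ch in names(genome$seq)) {
    s <- genome$seq[[ch]]
    n <- nchar(s)
    pos <- 2:(n - 1L)
    tri <- substring(s, pos - 1L, pos + 1L)
    mid <- substr(tri, 2L, 2L)
    flip <- !(mid %in% PYRIMIDINES)
    tri[flip] <- revcomp(tri[flip])
    df <- data.frame(chrom = ch, pos = pos, flip = flip,
                     stringsAsFactors = FALSE)
    sp <- split(df, tri)
    for (k in names(sp)) idx[[k]] <- rbind(idx[[k]], sp[[k]])
  }
  idx
}

## Reference base / triplet lookup.
ref_base <- function(genome, chrom, pos) {
  substring(genome$seq[chrom], pos, pos)
}

ref_triplet <- function(genome, chrom, pos) {
  substring(genome$seq[chrom], pos - 1L, pos + 1L)
}

## Gene containing each position (positions are always inside the tiling).
gene_at <- function(genome, chrom, pos) {
  gl <- genome$gene_length
  per <- nchar(genome$seq[[1]]) %/% gl
  ci <- match(chrom, names(genome$seq))
  gi <- (ci - 1L) * per + ((pos - 1L) %/% gl) + 1L
  genome$genes$gene[gi]
}
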