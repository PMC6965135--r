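#' Tabulate the 96-context substitution spectrum
#'
#' Counts single-base substitutions by trinucleotide context in the
#' pyrimidine frame (purine-reference substitutions are
#' reverse-complemented). Indels are excluded; loci at contig edges (no
#' flanking base) are excluded and reported in the `excluded` attribute. The
#' spectrum total therefore equals the number of SNVs minus edge exclusions.
#'
#' @param mutations data.frame with `chrom`, `pos`, `ref`, `alt` and
#'   optionally `kind` (rows with `kind != "snv"` are skipped; otherwise
#'   multi-base alleles are skipped).
#' @param reference named character vector of contig sequences (see
#'   [read_reference_fasta()]) or an `mseq_genome`.
#' @return named numeric vector of length 96 (class `mseq_spectrum` via
#'   attribute `total`), with attribute `excluded` listing skipped loci.
#' @export
count_contexts <- function(mutations, reference) {
  if (inherits(reference, "mseq_genome")) reference <- reference$seq
  labels <- context96_labels()
  counts <- stats::setNames(numeric(96L), labels)
  is_snv <- if ("kind" %in% names(mutations)) mutations$kind == "snv"
            else nchar(mutations$ref) == 1L & nchar(mutations$alt) == 1L
  m <- mutations[is_snv, , drop = FALSE]
  if (!all(m$chrom %in% names(reference))) {
    stop_mseq("reference does not cover all mutation contigs")
  }
  lens <- nchar(reference)[m$chrom]
  at_edge <- m$pos <= 1L | m$pos >= lens
  excluded <- m[at_edge, c("chrom", "pos"), drop = FALSE]
  m <- m[!at_edge, , drop = FALSE]
  if (nrow(m)) {
    tri <- substring(reference[m$chrom], m$pos - 1L, m$pos + 1L)
    if (any(substr(tri, 2L, 2L) != m$ref)) {
      stop_mseq("reference base does not match ref allele at some loci")
    }
    ctx <- classify_context96(m$ref, m$alt, tri)
    tab <- table(factor(ctx, levels = labels))
    counts <- counts + as.numeric(tab)
  }
  names(counts) <- labels
  attr(counts, "excluded") <- excluded
  attr(counts, "total") <- sum(counts)
  counts
}

#' Refit a spectrum against a signature catalog
#'
#' Finds nonnegative signature weights minimising the Euclidean distance
#' between the normalised spectrum and `catalog %*% weights`. Weights below
#' `cutoff` are zeroed and the remainder rescaled to preserve the fitted
#' total. The residual is the Euclidean norm of the reconstruction error.
#'
#' @param spectrum numeric vector of 96 counts or frequencies.
#' @param catalog 96 x S matrix of signature probability columns.
#' @param cutoff minimum weight retained (0 disables).
#' @return named numeric weight vector with attributes `residual` and
#'   `unassigned` (1 - sum of weights, floored at 0).
#' @export
fit_signatures <- function(spectrum, catalog, cutoff = 0) {
  if (length(spectrum) != nrow(catalog)) {
    stop_mseq("spectrum length does not match catalog rows")
  }
  tot <- sum(spectrum)
  if (tot <= 0) stop_mseq("all-zero spectrum cannot be refitted")
  y <- spectrum / tot
  fit <- pracma::lsqnonneg(as.matrix(catalog), as.numeric(y))
  w <- stats::setNames(fit$x, colnames(catalog))
  if (cutoff > 0 && any(w > 0 & w < cutoff)) {
    total_before <- sum(w)
    w[w < cutoff] <- 0
    if (sum(w) > 0) w <- w * total_before / sum(w)
  }
  attr(w, "residual") <- sqrt(sum((as.matrix(catalog) %*% w - y)^2))
  attr(w, "unassigned") <- max(0, 1 - sum(w))
  w
}

#' Report signature exposures across mutation groups
#'
#' Collects per-group exposure vectors into a matrix and masks signatures
#' whose weight stays below `report_min` in every group, the reporting rule
#' that only signatures contributing at least 5% of mutations in one of the
#' analysed groups are shown.
#'
#' @param exposures named list of weight vectors from [fit_signatures()]
#'   (one per mutation group, e.g. ubiquitous/heterogeneous).
#' @param report_min reporting threshold.
#' @return matrix signatures x groups restricted to reported signatures.
#' @export
report_exposures <- function(exposures, report_min = 0.05) {
  mat <- do.call(cbind, lapply(exposures, as.numeric))
  rownames(mat) <- names(exposures[[1]])
  colnames(mat) <- names(exposures)
  keep <- apply(mat, 1L, max) >= report_min
  mat[keep, , drop = FALSE]
}

#' Spectra per mutation group
#'
#' Convenience wrapper tabulating one spectrum per presence category (or any
#' grouping vector over sites).
#'
#' @param sites site table (must contain SNVs with `chrom`, `pos`, `ref`,
#'   `alt`).
#' @param groups character vector aligned with `sites` rows.
#' @param reference reference sequences.
#' @return named list of 96-vectors.
#' @export
spectra_by_group <- function(sites, groups, reference) {
  sp <- split(seq_len(nrow(sites)), groups)
  lapply(sp, function(i) count_contexts(sites[i, , drop = FALSE], reference))
}
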