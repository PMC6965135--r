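#' Allele-specific copy-number segment profile for one region
#'
#' @param region_id region label.
#' @param purity estimated tumour cell content in (0, 1].
#' @param segments data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive), `cn_total` (unrounded), `cn_major`, `cn_minor` (integers).
#' @return object of class `mseq_segprofile`.
#' @export
segment_profile <- function(region_id, purity, segments) {
  req <- c("chrom", "start", "end", "cn_total", "cn_major", "cn_minor")
  if (!all(req %in% names(segments))) {
    stop_mseq("segments need columns %s", paste(req, collapse = ", "))
  }
  if (purity <= 0 || purity > 1) stop_mseq("purity must be in (0, 1]")
  if (any(segments$cn_major < segments$cn_minor) ||
      any(segments$cn_minor < 0)) {
    stop_mseq("segments require cn_major >= cn_minor >= 0")
  }
  ## non-overlap within chromosome
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1L && any(s$start[-1] <= s$end[-nrow(s)])) {
      stop_mseq("overlapping segments on chromosome %s", ch)
    }
  }
  structure(list(region_id = region_id, purity = purity,
                 segments = segments[order(segments$chrom, segments$start), ]),
            class = "mseq_segprofile")
}

seg_lengths <- function(segments) segments$end - segments$start + 1

#' Ploidy: length-weighted mean copy number
#'
#' `Ploidy = sum(CN_total * SegmentLength) / sum(SegmentLength)` over all
#' segments, with `CN_total` the unrounded copy-number estimate and segment
#' length the genomic span between breakpoints.
#'
#' @param profile an `mseq_segprofile`.
#' @return numeric ploidy estimate.
#' @export
ploidy <- function(profile) {
  stopifnot(inherits(profile, "mseq_segprofile"))
  seg <- profile$segments
  if (nrow(seg) == 0L) stop_mseq("empty segment profile")
  len <- seg_lengths(seg)
  sum(seg$cn_total * len) / sum(len)
}

AUTOSOMES <- as.character(1:22)

#' Weighted genome instability index (wGII) and CIN status
#'
#' For each autosome present in the profile, computes the fraction of
#' covered bases in segments whose rounded integer total copy number differs
#' from the ploidy estimate rounded to the nearest integer state; the wGII
#' score is the unweighted mean of these per-chromosome fractions over the
#' autosomes present. Scores above 0.2 (strictly) flag chromosomal
#' instability (CIN). Aberrant cover is measured by length, not segment
#' count, so the score is invariant to splitting segments into equal-state
#' pieces. Autosomes absent from the profile are excluded from the mean.
#'
#' @param profile an `mseq_segprofile`.
#' @param ploidy_value optional ploidy override; defaults to
#'   [ploidy()] of the profile.
#' @return list with `score` (fraction), `cin` (logical), `per_chrom`
#'   (named vector of per-chromosome aberrant fractions).
#' @export
wgii <- function(profile, ploidy_value = NULL) {
  stopifnot(inherits(profile, "mseq_segprofile"))
  seg <- profile$segments
  seg <- seg[sub("^chr", "", seg$chrom) %in% AUTOSOMES, , drop = FALSE]
  if (nrow(seg) == 0L) stop_mseq("no autosomal segments in profile")
  pl <- ploidy_value %||% ploidy(profile)
  pl_int <- round_half_up(pl)
  len <- seg_lengths(seg)
  aberrant <- round_half_up(seg$cn_total) != pl_int
  per_chrom <- vapply(split(seq_len(nrow(seg)), sub("^chr", "", seg$chrom)),
                      function(i) {
                        sum(len[i][aberrant[i]]) / sum(len[i])
                      }, numeric(1))
  score <- mean(per_chrom)
  list(score = score, cin = score > 0.2, per_chrom = per_chrom)
}

#' Detect loss of heterozygosity over catalog genes
#'
#' A locus shows LOH when its minor copy number is 0 while at least one major
#' copy remains. Genes outside segment coverage are reported unassessable.
#'
#' @param profile an `mseq_segprofile`.
#' @param gene_catalog data.frame with `gene`, `chrom`, `start`, `end`.
#' @return data.frame with `region`, `gene`, `loh` (logical) and `status`
#'   (`loh`, `no_loh` or `unassessable`).
#' @export
detect_loh <- function(profile, gene_catalog) {
  stopifnot(inherits(profile, "mseq_segprofile"))
  seg <- profile$segments
  out <- lapply(seq_len(nrow(gene_catalog)), function(i) {
    g <- gene_catalog[i, ]
    hit <- seg$chrom == g$chrom & seg$start <= g$start & seg$end >= g$end
    if (!any(hit)) {
      return(data.frame(region = profile$region_id, gene = g$gene,
                        loh = NA, status = "unassessable",
                        stringsAsFactors = FALSE))
    }
    s <- seg[which(hit)[1], ]
    is_loh <- s$cn_minor == 0L && s$cn_major >= 1L
    data.frame(region = profile$region_id, gene = g$gene, loh = is_loh,
               status = if (is_loh) "loh" else "no_loh",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Aggregate per-region events to tumour-wide (ubiquitous) calls
#'
#' An event (e.g. LOH of a gene) is ubiquitous when present in every region
#' of the tumour.
#'
#' @param event_tables list of [detect_loh()]-style data.frames, one per
#'   region.
#' @return data.frame with `gene`, `n_regions`, `n_with_event`, `ubiquitous`.
#' @export
ubiquitous_events <- function(event_tables) {
  all_ev <- do.call(rbind, event_tables)
  genes <- unique(all_ev$gene)
  out <- lapply(genes, function(g) {
    e <- all_ev[all_ev$gene == g, ]
    assessable <- e[!is.na(e$loh), ]
    data.frame(gene = g, n_regions = nrow(e),
               n_with_event = sum(assessable$loh),
               ubiquitous = nrow(e) > 0L && all(!is.na(e$loh)) && all(e$loh),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
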