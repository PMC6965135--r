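#' Mutation copy number from VAF, purity and local total copy number
#'
#' `MUT_CN = VAF * (1/p) * (p * CN_total + 2 * (1 - p))`, the average number
#' of mutated chromosome copies per tumour cell, where `p` is the tumour
#' cell content of the sample and `CN_total` the (unrounded) total copy
#' number at the locus.
#'
#' @param vaf variant allele frequency.
#' @param p tumour purity in (0, 1].
#' @param cn_total total copy number at the locus (> 0).
#' @return numeric mutation copy number (vectorised).
#' @export
#' @examples
#' mutation_copy_number(0.5, 1, 2)    # 1
#' mutation_copy_number(0.25, 0.5, 2) # 1
mutation_copy_number <- function(vaf, p, cn_total) {
  if (any(p <= 0) || any(p > 1)) stop_mseq("purity must be in (0, 1]")
  if (any(cn_total <= 0)) stop_mseq("cn_total must be positive")
  vaf * (1 / p) * (p * cn_total + 2 * (1 - p))
}

#' Multiplicity and cancer cell fraction from mutation copy number
#'
#' Multiplicity is the nearest integer to `MUT_CN`, clamped to
#' `[1, cn_major]`; the CCF is `MUT_CN / m`, reported capped at 1 with the
#' raw (uncapped) value retained.
#'
#' @param mut_cn mutation copy number (>= 0).
#' @param cn_major major allele copy number at the locus (>= 1).
#' @return data.frame with `m` (integer multiplicity), `ccf` (capped at 1)
#'   and `ccf_raw`.
#' @export
#' @examples
#' ccf_estimate(1.8, 2)  # m = 2, ccf = 0.9
ccf_estimate <- function(mut_cn, cn_major) {
  if (any(mut_cn < 0)) stop_mseq("mut_cn must be nonnegative")
  if (any(cn_major < 1)) stop_mseq("cn_major must be >= 1")
  m <- as.integer(clamp(round_half_up(mut_cn), 1L, cn_major))
  raw <- mut_cn / m
  data.frame(m = m, ccf = pmin(raw, 1), ccf_raw = raw)
}

## Locate the segment covering each locus in a region profile; returns row
## indices into profile$segments (NA when uncovered).
segment_at <- function(profile, chrom, pos) {
  seg <- profile$segments
  idx <- rep(NA_integer_, length(chrom))
  for (ch in unique(chrom)) {
    rows <- which(seg$chrom == ch)
    if (!length(rows)) next
    sel <- which(chrom == ch)
    s <- seg[rows, ]
    j <- findInterval(pos[sel], s$start)
    ok <- j >= 1L & pos[sel] <= s$end[pmax(j, 1L)]
    idx[sel[ok]] <- rows[j[ok]]
  }
  idx
}

#' Per-mutation, per-region CCF matrix
#'
#' For every retained mutation and every region where it is present,
#' computes VAF, mutation copy number, integer multiplicity and cancer cell
#' fraction using the region's purity and the copy-number segment covering
#' the locus. CCF is undefined (NA) where the mutation is absent.
#'
#' @param presence an `mseq_presence` object from [two_tier_call()].
#' @param segments named list of [segment_profile()] objects (one per
#'   region).
#' @return object of class `mseq_ccf`: list of matrices `vaf`, `mut_cn`,
#'   `m`, `ccf`, `ccf_raw` (mutations x regions) plus the site table.
#' @export
compute_ccf <- function(presence, segments) {
  stopifnot(inherits(presence, "mseq_presence"))
  regions <- colnames(presence$presence)
  missing_r <- setdiff(regions, names(segments))
  if (length(missing_r)) {
    stop_mseq("no segment profile for region(s): %s",
              paste(missing_r, collapse = ", "))
  }
  sites <- presence$sites
  n <- nrow(sites)
  mk <- function() matrix(NA_real_, n, length(regions),
                          dimnames = list(sites$site_id, regions))
  vaf <- presence$vaf
  mut_cn <- mk(); mmat <- mk(); ccf <- mk(); ccf_raw <- mk()
  for (r in regions) {
    prof <- segments[[r]]
    si <- segment_at(prof, sites$chrom, sites$pos)
    pres <- presence$presence[, r] & !is.na(si)
    if (!any(pres)) next
    seg <- prof$segments[si[pres], ]
    mc <- mutation_copy_number(vaf[pres, r], prof$purity, seg$cn_total)
    est <- ccf_estimate(pmax(mc, 0), pmax(seg$cn_major, 1L))
    mut_cn[pres, r] <- mc
    mmat[pres, r] <- est$m
    ccf[pres, r] <- est$ccf
    ccf_raw[pres, r] <- est$ccf_raw
  }
  structure(list(sites = sites, vaf = vaf, mut_cn = mut_cn, m = mmat,
                 ccf = ccf, ccf_raw = ccf_raw,
                 presence = presence$presence,
                 category = presence$category),
            class = "mseq_ccf")
}

#' Split mutation-region observations into clonal and subclonal
#'
#' A mutation is clonal in a region when its CCF there is at least
#' `threshold` (>= 0.7 by default).
#'
#' @param ccf an `mseq_ccf` object or a numeric CCF matrix.
#' @param threshold CCF at or above which an observation is clonal.
#' @return logical matrix (NA where CCF undefined).
#' @export
split_clonal <- function(ccf, threshold = 0.7) {
  m <- if (inherits(ccf, "mseq_ccf")) ccf$ccf else ccf
  m >= threshold
}

#' Time a copy-number gain from mutation multiplicities
#'
#' An early gain (preceding most mutation accrual) leaves the bulk of
#' mutations on a single copy; a late gain duplicates mutations that were
#' already present on the gained allele. The statistic is the fraction of
#' ubiquitous mutations in the gained segment carrying the full major copy
#' number; the gain is labelled `early` when that fraction is at most
#' `early_cutoff` (near-complete absence of fully amplified mutations) and
#' `late` otherwise. Segments with fewer than `min_mutations` informative
#' mutations are unassessable.
#'
#' @param multiplicities integer vector of multiplicities of ubiquitous
#'   mutations in the segment (one region).
#' @param cn_major major copy number of the gained segment (>= 2).
#' @param min_mutations minimum informative mutations.
#' @param early_cutoff threshold on the full-multiplicity fraction.
#' @return list with `label` (`early`/`late`/`unassessable`), `stat`, `n`.
#' @export
time_gain <- function(multiplicities, cn_major, min_mutations = 10L,
                      early_cutoff = 0.05) {
  if (cn_major < 2L) stop_mseq("gain timing requires cn_major >= 2")
  n <- length(multiplicities)
  if (n < min_mutations) {
    return(list(label = "unassessable", stat = NA_real_, n = n))
  }
  stat <- mean(multiplicities == cn_major)
  list(label = if (stat <= early_cutoff) "early" else "late",
       stat = stat, n = n)
}

#' Time all gained segments of a region
#'
#' Convenience wrapper applying [time_gain()] to every segment with
#' `cn_major >= 2` in a region profile, using the multiplicities of
#' ubiquitous mutations falling in each segment.
#'
#' @param ccf an `mseq_ccf` object.
#' @param profile the region's [segment_profile()].
#' @param region region id.
#' @param ... passed to [time_gain()].
#' @return data.frame with one row per gained segment.
#' @export
time_region_gains <- function(ccf, profile, region, ...) {
  seg <- profile$segments
  gained <- which(seg$cn_major >= 2L)
  ub <- names(ccf$category)[ccf$category == "ubiquitous"]
  rows <- lapply(gained, function(i) {
    s <- seg[i, ]
    in_seg <- ccf$sites$site_id %in% ub &
      ccf$sites$chrom == s$chrom &
      ccf$sites$pos >= s$start & ccf$sites$pos <= s$end
    mult <- ccf$m[in_seg, region]
    mult <- mult[!is.na(mult)]
    tg <- time_gain(mult, s$cn_major, ...)
    data.frame(region = region, chrom = s$chrom, start = s$start,
               end = s$end, cn_major = s$cn_major, label = tg$label,
               stat = tg$stat, n = tg$n, stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(region = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      cn_major = integer(0), label = character(0),
                      stat = numeric(0), n = integer(0)))
  }
  do.call(rbind, rows)
}
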