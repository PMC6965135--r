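## Multi-region variant tables are plain data.frames with one row per
## candidate site and paired per-region columns `<region>_depth` /
## `<region>_alt`, plus `normal_depth` / `normal_alt`.

#' Region identifiers of a site table
#'
#' @param sites multi-sample variant data.frame.
#' @return character vector of region ids, in column order.
#' @export
region_ids <- function(sites) {
  d <- grep("_depth$", names(sites), value = TRUE)
  d <- setdiff(d, "normal_depth")
  sub("_depth$", "", d)
}

vaf_matrix <- function(sites, regions = region_ids(sites)) {
  v <- matrix(0, nrow = nrow(sites), ncol = length(regions),
              dimnames = list(sites$site_id, regions))
  for (r in regions) {
    depth <- sites[[paste0(r, "_depth")]]
    alt <- sites[[paste0(r, "_alt")]]
    v[, r] <- ifelse(depth > 0L, alt / depth, 0)
  }
  v
}

#' Depth and germline quality filter
#'
#' Applies the multi-region quality filters in a fixed, documented order so
#' that each rejected site carries a single deterministic reason:
#' sex-chromosome exclusion, then minimum tumour depth in every region, then
#' minimum germline depth, then germline variant evidence. A site is rejected
#' on germline evidence only when the germline VAF exceeds `max_germline_vaf`
#' *and* the germline alt count exceeds `max_germline_alt` (both conditions
#' must hold).
#'
#' @param sites site table.
#' @param min_region_depth minimum depth required in every tumour region.
#' @param min_germline_depth minimum depth in the matched normal.
#' @param max_germline_vaf germline VAF above which (together with the count
#'   condition) a site is rejected.
#' @param max_germline_alt germline alt-read count above which (together with
#'   the VAF condition) a site is rejected.
#' @return list with `pass` (retained site table) and `fail` (data.frame
#'   `site_id`, `reason`).
#' @export
quality_filter <- function(sites, min_region_depth = 70L,
                           min_germline_depth = 20L,
                           max_germline_vaf = 0.02,
                           max_germline_alt = 2L) {
  regions <- region_ids(sites)
  if (!length(regions)) stop_mseq("site table has no region depth columns")
  depth <- as.matrix(sites[paste0(regions, "_depth")])
  reason <- rep(NA_character_, nrow(sites))

  sex <- sites$chrom %in% c("X", "Y", "chrX", "chrY")
  reason[sex] <- "sex_chromosome"

  low_t <- apply(depth < min_region_depth, 1L, any)
  reason[is.na(reason) & low_t] <- "tumour_depth"

  low_g <- sites$normal_depth < min_germline_depth
  reason[is.na(reason) & low_g] <- "germline_depth"

  gvaf <- ifelse(sites$normal_depth > 0L,
                 sites$normal_alt / sites$normal_depth, 0)
  germ <- gvaf > max_germline_vaf & sites$normal_alt > max_germline_alt
  reason[is.na(reason) & germ] <- "germline_evidence"

  list(pass = sites[is.na(reason), , drop = FALSE],
       fail = data.frame(site_id = sites$site_id[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE))
}

#' Panel-of-normals (cross-germline) filter
#'
#' Removes a site when the fraction of panel normals carrying it at
#' VAF >= `vaf_min` is at least `prevalence`, the rule used to strip
#' recurrent alignment artifacts: with a 14-normal panel and the defaults, 3
#' carriers (21.4%) reject a site while 2 carriers (14.3%) retain it.
#'
#' @param sites site table.
#' @param panel sites x normals VAF matrix (rownames = site ids); sites
#'   absent from the panel are retained.
#' @param vaf_min VAF at which a normal counts as a carrier.
#' @param prevalence carrier fraction at or above which the site is rejected.
#' @return list with `pass` and `fail` (data.frame `site_id`, `reason`,
#'   `carrier_fraction`).
#' @export
cross_germline_filter <- function(sites, panel, vaf_min = 0.02,
                                  prevalence = 0.20) {
  if (is.null(panel) || nrow(panel) == 0L) stop_mseq("panel must be nonempty")
  idx <- match(sites$site_id, rownames(panel))
  frac <- rep(0, nrow(sites))
  has <- !is.na(idx)
  frac[has] <- rowMeans(panel[idx[has], , drop = FALSE] >= vaf_min)
  rej <- frac >= prevalence
  list(pass = sites[!rej, , drop = FALSE],
       fail = data.frame(site_id = sites$site_id[rej],
                         reason = rep("panel_of_normals", sum(rej)),
                         carrier_fraction = frac[rej],
                         stringsAsFactors = FALSE))
}

#' Two-tier multi-region mutation calling
#'
#' Tier 1 retains a mutation if at least one tumour region reaches a VAF of
#' `tier1_vaf` (>=, a minimum). Tier 2 then scores the mutation present in
#' each individual region whose VAF strictly exceeds `tier2_vaf`. Retained
#' mutations are categorised from the presence pattern: ubiquitous (all
#' regions), private (exactly one region), shared (otherwise). Zero-depth
#' regions are treated as VAF 0.
#'
#' @param sites quality-filtered site table.
#' @param tier1_vaf minimum VAF required in at least one region.
#' @param tier2_vaf per-region presence threshold (strict).
#' @return object of class `mseq_presence`: list with `sites` (retained
#'   rows), `presence` (logical matrix sites x regions), `vaf` (matrix),
#'   `category` (named character), `rejected` (site ids failing tier 1).
#' @export
two_tier_call <- function(sites, tier1_vaf = 0.05, tier2_vaf = 0.025) {
  regions <- region_ids(sites)
  vaf <- vaf_matrix(sites, regions)
  keep <- if (nrow(sites) == 0L) logical(0) else
    apply(vaf, 1L, max) >= tier1_vaf
  pres <- vaf[keep, , drop = FALSE] > tier2_vaf
  category <- presence_category(pres)
  structure(list(
    sites = sites[keep, , drop = FALSE],
    presence = pres,
    vaf = vaf[keep, , drop = FALSE],
    category = category,
    rejected = sites$site_id[!keep]
  ), class = "mseq_presence")
}

presence_category <- function(pres) {
  n <- rowSums(pres)
  out <- ifelse(n == ncol(pres), "ubiquitous",
                ifelse(n == 1L, "private",
                       ifelse(n == 0L, "absent", "shared")))
  stats::setNames(out, rownames(pres))
}

#' @export
print.mseq_presence <- function(x, ...) {
  cat(sprintf("Presence matrix: %d mutations x %d regions\n",
              nrow(x$presence), ncol(x$presence)))
  print(table(x$category))
  invisible(x)
}

#' Summarise mutation intratumour heterogeneity counts
#'
#' Counts non-silent mutations (default: everything except synonymous calls)
#' and splits them into ubiquitous and heterogeneous (shared + private), with
#' percentages relative to the non-silent total.
#'
#' @param presence an `mseq_presence` object.
#' @param consequence_filter consequences counted as non-silent.
#' @return one-row data.frame with counts and percentages.
#' @export
categorize_counts <- function(presence,
                              consequence_filter = c("missense", "stop_gained",
                                                     "stop_lost", "frameshift",
                                                     "splice_site")) {
  stopifnot(inherits(presence, "mseq_presence"))
  sel <- presence$sites$consequence %in% consequence_filter
  cat <- presence$category[sel]
  n_ub <- sum(cat == "ubiquitous")
  n_sh <- sum(cat == "shared")
  n_pr <- sum(cat == "private")
  n_het <- n_sh + n_pr
  total <- n_ub + n_het
  data.frame(
    n_nonsilent = total, n_ubiquitous = n_ub, n_shared = n_sh,
    n_private = n_pr, n_heterogeneous = n_het,
    pct_ubiquitous = if (total > 0L) 100 * n_ub / total else 0,
    pct_heterogeneous = if (total > 0L) 100 * n_het / total else 0
  )
}

#' Flag likely driver mutations
#'
#' A mutation is flagged as a likely driver when any of three rules fires:
#' (1) the exact protein change is known for that gene in the catalog;
#' (2) it is a disrupting mutation (frameshift, nonsense/stop-gained or
#' splice-site) in a tumour suppressor gene; (3) it alters a residue position
#' known to be altered, with a different amino-acid change.
#'
#' @param annotation data.frame with `gene`, `consequence`, `protein_change`.
#' @param catalog driver catalog (see [driver_catalog()]).
#' @return `annotation` with added `likely_driver` (logical) and `rule`
#'   (`known_change`, `disrupting_tsg`, `hotspot_position` or `NA`).
#' @export
classify_driver <- function(annotation, catalog = driver_catalog()) {
  known_cons <- c("missense", "synonymous", "stop_gained", "stop_lost",
                  "frameshift", "splice_site")
  bad <- setdiff(unique(annotation$consequence), known_cons)
  if (length(bad)) {
    stop_mseq("unknown consequence vocabulary: %s", paste(bad, collapse = ", "))
  }
  disrupting <- c("frameshift", "stop_gained", "splice_site")
  n <- nrow(annotation)
  rule <- rep(NA_character_, n)
  ci <- match(annotation$gene, catalog$gene)
  pos <- suppressWarnings(as.integer(gsub("[^0-9]", "",
                                          annotation$protein_change %||% "")))
  for (i in seq_len(n)) {
    if (is.na(ci[i])) next
    entry <- catalog[ci[i], ]
    changes <- strsplit(entry$known_changes, ",")[[1]]
    positions <- suppressWarnings(as.integer(strsplit(entry$known_positions,
                                                      ",")[[1]]))
    if (!is.na(annotation$protein_change[i]) &&
        annotation$protein_change[i] %in% changes) {
      rule[i] <- "known_change"
    } else if (annotation$consequence[i] %in% disrupting &&
               identical(entry$role, "tsg")) {
      rule[i] <- "disrupting_tsg"
    } else if (!is.na(pos[i]) && length(positions) && pos[i] %in% positions &&
               annotation$consequence[i] != "synonymous") {
      rule[i] <- "hotspot_position"
    }
  }
  annotation$likely_driver <- !is.na(rule)
  annotation$rule <- rule
  annotation
}
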