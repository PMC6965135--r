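NONSILENT <- c("missense", "stop_gained", "stop_lost", "frameshift",
               "splice_site")

#' Single-region versus multi-region clonality comparison
#'
#' Quantifies the "illusion of clonality": per region, the total non-silent
#' mutation load and the clonal load (CCF >= `threshold` in that region) are
#' compared against the number of ubiquitous (multi-region) mutations, with
#' percent differences `(single_region - ubiquitous) / ubiquitous * 100`.
#' For driver-flagged mutations, a mutation-region observation counts toward
#' the illusion when the mutation is heterogeneous tumour-wide (shared or
#' private) yet appears clonal in that single region; per-gene and overall
#' illusion percentages are reported over driver observations.
#'
#' @param ccf an `mseq_ccf` object.
#' @param annotation data.frame with `site_id`, `gene`, `likely_driver`
#'   (see [classify_driver()]).
#' @param threshold single-region clonality CCF threshold.
#' @param consequence_filter consequences counted as non-silent.
#' @return list (class `mseq_clonality_cmp`) with `per_region` (data.frame),
#'   `per_gene` (data.frame), `overall_illusion_pct`, `n_driver_obs`.
#' @export
illusion_of_clonality <- function(ccf, annotation, threshold = 0.7,
                                  consequence_filter = NONSILENT) {
  stopifnot(inherits(ccf, "mseq_ccf"))
  regions <- colnames(ccf$presence)
  nonsil <- ccf$sites$consequence %in% consequence_filter
  cat <- ccf$category
  clonal <- split_clonal(ccf, threshold)
  n_ub <- sum(cat[nonsil] == "ubiquitous")
  per_region <- do.call(rbind, lapply(regions, function(r) {
    pres <- ccf$presence[, r] & nonsil
    total <- sum(pres)
    clo <- sum(pres & clonal[, r] %in% TRUE)
    data.frame(
      region = r, total_load = total, clonal_load = clo,
      ubiquitous_load = n_ub,
      pct_diff_total = if (n_ub > 0) (total - n_ub) / n_ub * 100 else NA_real_,
      pct_diff_clonal = if (n_ub > 0) (clo - n_ub) / n_ub * 100 else NA_real_,
      stringsAsFactors = FALSE)
  }))

  ## driver-level illusion over heterogeneous (shared/private) observations
  ann <- annotation[annotation$likely_driver %in% TRUE, , drop = FALSE]
  het_ids <- names(cat)[cat %in% c("shared", "private")]
  obs <- list()
  for (mid in intersect(ann$site_id, het_ids)) {
    g <- ann$gene[match(mid, ann$site_id)]
    for (r in regions[ccf$presence[mid, ]]) {
      obs[[length(obs) + 1L]] <- data.frame(
        mutation_id = mid, gene = g, region = r,
        illusory = isTRUE(clonal[mid, r]), stringsAsFactors = FALSE)
    }
  }
  if (length(obs)) {
    obs <- do.call(rbind, obs)
    per_gene <- do.call(rbind, lapply(split(obs, obs$gene), function(o) {
      data.frame(gene = o$gene[1], n_obs = nrow(o),
                 n_illusory = sum(o$illusory),
                 illusion_pct = 100 * mean(o$illusory),
                 stringsAsFactors = FALSE)
    }))
    rownames(per_gene) <- NULL
    overall <- 100 * mean(obs$illusory)
    n_obs <- nrow(obs)
  } else {
    per_gene <- data.frame(gene = character(0), n_obs = integer(0),
                           n_illusory = integer(0),
                           illusion_pct = numeric(0))
    overall <- NA_real_
    n_obs <- 0L
  }
  structure(list(per_region = per_region, per_gene = per_gene,
                 overall_illusion_pct = overall, n_driver_obs = n_obs),
            class = "mseq_clonality_cmp")
}

#' Fraction of subclonal mutations per region
#'
#' The per-region fraction of present mutations with CCF below `threshold`,
#' plus the median across regions.
#'
#' @param ccf an `mseq_ccf` object.
#' @param threshold clonality threshold.
#' @return list with `per_region` (named fractions) and `median`.
#' @export
subclonal_fraction <- function(ccf, threshold = 0.7) {
  stopifnot(inherits(ccf, "mseq_ccf"))
  regions <- colnames(ccf$presence)
  per <- vapply(regions, function(r) {
    pres <- ccf$presence[, r]
    if (!any(pres)) stop_mseq("region %s has no present mutations", r)
    mean(ccf$ccf[pres, r] < threshold)
  }, numeric(1))
  list(per_region = per, median = stats::median(per))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_mseq("stage %s: %s", name, conditionMessage(e))
  })
}

#' Run the full multi-region analysis pipeline
#'
#' Executes simulation (when given a config), variant filtering, presence
#' categorisation, copy-number metrics, CCF estimation, clone-tree
#' reconstruction, conflict explanation, parallel-evolution detection,
#' signature refitting, compartment dN/dS and the clonality report, writing
#' all result tables plus a run manifest (file checksums, config hash, seed)
#' to `out_dir`. Reruns with the same config are byte-identical.
#'
#' @param config an [sim_config()]; its seed drives all randomness.
#' @param out_dir output directory (created if needed).
#' @param inputs optional list with `sites`, `segments`, `panel` and
#'   `reference` to analyse pre-existing data instead of simulating.
#' @param catalog signature catalog used for refitting (defaults to the
#'   config's catalog).
#' @param drivers driver catalog for [classify_driver()].
#' @return invisibly, a list with all intermediate results and `manifest`.
#' @export
run_pipeline <- function(config = NULL, out_dir, inputs = NULL,
                         catalog = NULL, drivers = driver_catalog()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config) && is.null(inputs)) {
    stop_mseq("either a simulation config or an inputs list is required")
  }

  if (!is.null(inputs)) {
    sites <- inputs$sites; segments <- inputs$segments
    panel <- inputs$panel; reference <- inputs$reference
    genome <- NULL
  } else {
    sim <- run_stage("simulate", {
      s <- simulate_tumour(config)
      s$panel <- simulate_normal_panel(config, s$sites)
      s
    })
    sites <- sim$sites; segments <- sim$segments; panel <- sim$panel
    genome <- config$genome; reference <- genome$seq
  }
  catalog <- catalog %||% (if (!is.null(config)) config$catalog
                           else synthetic_signature_catalog())

  vres <- run_stage("variants", {
    qf <- quality_filter(sites)
    cg <- cross_germline_filter(qf$pass, panel)
    presence <- two_tier_call(cg$pass)
    ann <- classify_driver(presence$sites[c("site_id", "gene", "consequence",
                                            "protein_change")], drivers)
    list(qf = qf, cg = cg, presence = presence, annotation = ann,
         counts = categorize_counts(presence))
  })

  cna_res <- run_stage("cna", {
    if (is.null(segments)) stop_mseq("segment profiles are missing")
    per_region <- lapply(segments, function(p) {
      w <- wgii(p)
      data.frame(region = p$region_id, purity = p$purity,
                 ploidy = ploidy(p), wgii = w$score, cin = w$cin,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_region)
  })

  ccf <- run_stage("clonality", compute_ccf(vres$presence, segments))
  timing <- run_stage("clonality", {
    do.call(rbind, lapply(names(segments), function(r) {
      time_region_gains(ccf, segments[[r]], r)
    }))
  })

  phy <- run_stage("phylo", {
    drv_ids <- vres$annotation$site_id[vres$annotation$likely_driver]
    clusters <- cluster_ccfs(ccf, drivers = drv_ids)
    tree <- build_tree(clusters)
    conflicts <- explain_conflicts(ccf, tree, segments)
    parallel <- detect_parallel_evolution(tree, vres$annotation)
    list(clusters = clusters, tree = tree, conflicts = conflicts,
         parallel = parallel)
  })

  sig <- run_stage("signatures", {
    grp <- ifelse(ccf$category == "ubiquitous", "ubiquitous", "heterogeneous")
    snv <- ccf$sites$kind == "snv"
    spectra <- spectra_by_group(ccf$sites[snv, ], grp[snv], reference)
    exposures <- lapply(spectra, fit_signatures, catalog = catalog)
    list(spectra = spectra, exposures = exposures,
         reported = report_exposures(exposures))
  })

  sel <- if (is.null(genome)) NULL else run_stage("selection", {
    cds <- gene_sequences(genome)
    model <- build_opportunity(cds)
    snv <- ccf$sites[ccf$sites$kind == "snv", ]
    tri <- substring(reference[snv$chrom], snv$pos - 1L, snv$pos + 1L)
    muts <- data.frame(
      context96 = classify_context96(snv$ref, snv$alt, tri),
      syn = snv$consequence == "synonymous",
      compartment = unname(ccf$category[snv$site_id]),
      stringsAsFactors = FALSE)
    dnds(muts, model)
  })

  rep_res <- run_stage("report", {
    list(illusion = illusion_of_clonality(ccf, vres$annotation),
         subclonal = subclonal_fraction(ccf))
  })

  manifest <- run_stage("report", {
    write_outputs(out_dir, sites, segments, vres, cna_res, ccf, timing,
                  phy, sig, sel, rep_res, config)
  })

  invisible(list(sites = sites, segments = segments, variants = vres,
                 cna = cna_res, ccf = ccf, timing = timing, phylo = phy,
                 signatures = sig, dnds = sel, report = rep_res,
                 manifest = manifest))
}

## Coding sequences of every gene tile (the toy genome is fully coding).
gene_sequences <- function(genome) {
  g <- genome$genes
  out <- substring(genome$seq[g$chrom], g$start, g$end)
  names(out) <- g$gene
  out
}

ccf_long_table <- function(ccf) {
  regions <- colnames(ccf$presence)
  do.call(rbind, lapply(regions, function(r) {
    pres <- which(ccf$presence[, r])
    data.frame(mutation_id = rownames(ccf$presence)[pres], region = r,
               vaf = ccf$vaf[pres, r], mut_cn = ccf$mut_cn[pres, r],
               m = ccf$m[pres, r], ccf = ccf$ccf[pres, r],
               clonal = ccf$ccf[pres, r] >= 0.7,
               stringsAsFactors = FALSE)
  }))
}

write_outputs <- function(out_dir, sites, segments, vres, cna_res, ccf,
                          timing, phy, sig, sel, rep_res, config) {
  fp <- function(x) file.path(out_dir, x)
  write_sites_tsv(sites, fp("sites.tsv"))
  for (r in names(segments)) {
    write_segments_tsv(segments[[r]], fp(sprintf("segments_%s.tsv", r)))
  }
  write_presence_tsv(vres$presence, fp("presence.tsv"))
  utils::write.table(vres$counts, fp("mutation_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cna_res, fp("cna_metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ccf_long_table(ccf), fp("ccf.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(timing) && nrow(timing)) {
    utils::write.table(timing, fp("gain_timing.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tree_newick(phy$tree, fp("tree.nwk"))
  jsonlite::write_json(list(
    error_score = phy$tree$error_score,
    valid = phy$tree$valid,
    parent = phy$tree$parent,
    clusters = lapply(phy$tree$clusters$clusters, function(cl) {
      list(id = cl$id, n_mutations = length(cl$members),
           centroid = as.list(round(cl$centroid, 6)))
    }),
    unassigned = length(phy$tree$clusters$unassigned)
  ), fp("tree.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  utils::write.table(phy$conflicts, fp("conflicts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(phy$parallel, fp("parallel_events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_spectrum_tsv(do.call(cbind, sig$spectra), fp("spectra.tsv"))
  exp_mat <- do.call(cbind, lapply(sig$exposures, as.numeric))
  rownames(exp_mat) <- names(sig$exposures[[1]])
  write_spectrum_tsv(exp_mat, fp("exposures.tsv"))
  if (!is.null(sel)) {
    utils::write.table(as.data.frame(sel), fp("dnds.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(list(
    per_region = rep_res$illusion$per_region,
    per_gene = rep_res$illusion$per_gene,
    overall_illusion_pct = rep_res$illusion$overall_illusion_pct,
    subclonal_fraction = as.list(rep_res$subclonal$per_region),
    subclonal_median = rep_res$subclonal$median
  ), fp("report.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(
    package = "mseqevo",
    version = as.character(utils::packageVersion("mseqevo")),
    seed = if (!is.null(config)) config$seed else NA,
    config_hash = if (!is.null(config)) config_hash(config) else NA,
    files = stats::setNames(as.list(unname(sums)), files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

## Stable hash of the scalar configuration (the genome and catalog are
## derived deterministically from the seed, so hashing the scalars plus the
## seed identifies the run).
config_hash <- function(config) {
  scalars <- config[!(names(config) %in% c("genome", "catalog"))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(scalars, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
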