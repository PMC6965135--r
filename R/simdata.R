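#' Simulation configuration for a branched multi-region tumour
#'
#' Assembles and validates the parameters of the ground-truthed tumour
#' simulator. Defaults emulate the mismatch-repair-deficient
#' gastro-oesophageal regime: ~700 truncal mutations, a branched clone tree
#' contributing ~1100 heterogeneous mutations, 20-34% indels, MSI-type
#' signature mixtures that differ between trunk and branches, target depth
#' 200x in tumour regions and 100x in the matched normal, and purities
#' between 0.2 and 0.9.
#'
#' @param seed master RNG seed; every stochastic step derives its stream from
#'   it, so a config is fully reproducible.
#' @param n_regions number of primary tumour regions (`R1..Rn`).
#' @param n_lymph_nodes additional lymph-node regions (`LN1..`), treated as
#'   regions throughout the analysis.
#' @param clone_tree optional data.frame (`clone`, `parent`, `n_mutations`)
#'   describing the clone tree; `parent = 0` marks the root (truncal) clone,
#'   whose `n_mutations` is overridden by `truncal_mutations`. When `NULL` a
#'   random tree with `n_clones` clones and per-branch mutation counts drawn
#'   from `mut_range` is generated.
#' @param n_clones,mut_range random-tree parameters (see `clone_tree`).
#' @param truncal_mutations mutations on the trunk (root clone).
#' @param indel_fraction fraction of mutations simulated as context-free
#'   frameshift indels.
#' @param signature_mix_trunk,signature_mix_branch named weight vectors over
#'   catalog columns (normalised to sum to 1) for truncal and branch SNVs.
#' @param purity_range per-region purity drawn uniformly from this interval.
#' @param mean_depth,normal_depth Poisson mean sequencing depth in tumour
#'   regions and the matched normal.
#' @param genome an [toy_genome()] object (default built from `seed`).
#' @param catalog 96 x S signature catalog matrix (default
#'   [synthetic_signature_catalog()]).
#' @param cna_events optional data.frame (`clone`, `chrom`, `cn_major`,
#'   `cn_minor`, `timing`) of copy-number events; `timing` is
#'   `"before_mutations"` (gain precedes the clone's mutations, so mutations
#'   sit on single copies) or `"after_mutations"`. At most one event per
#'   chromosome; events are regionally clonal where the carrying clone
#'   dominates.
#' @param loss_events optional data.frame (`clone`, `chrom`): a subclonal
#'   copy loss that deletes previously acquired (ancestral) mutations on the
#'   lost allele in regions dominated by that clone.
#' @param panel_size number of unmatched normals in the panel.
#' @param artifact_rate fraction of recurrent-artifact sites added to the
#'   variant table (relative to the number of real mutations).
#' @param artifact_prevalence fraction of panel normals expected to carry an
#'   artifact site at VAF >= 2%.
#' @param error_rate per-base sequencing error rate adding alt reads at
#'   wild-type sites.
#' @param normal_contamination fraction of tumour-derived reads contaminating
#'   the matched normal (exercises the germline evidence filter).
#' @param min_clone_ccf floor on a clone's cancer-cell fraction in regions
#'   where it is present (detectability floor of the generated truth).
#' @param depth_override set to `Inf` for noiseless data: allele counts are
#'   rendered at depth 1e6 with `alt = expected VAF * depth` (rounded).
#' @param clone_regions optional list mapping clone id to the region ids it
#'   occupies (overrides the random spatial assignment). Region sets must
#'   nest along lineages and be disjoint between sibling subtrees.
#' @param clone_ccf optional clone x region CCF matrix overriding the random
#'   draw; validated against the lineage sum rule.
#' @return object of class `mseq_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_regions = 7L,
                       n_lymph_nodes = 0L,
                       clone_tree = NULL,
                       n_clones = 5L,
                       mut_range = c(150L, 400L),
                       truncal_mutations = 700L,
                       indel_fraction = 0.27,
                       signature_mix_trunk = c(S6 = 0.35, S15 = 0.35, S1 = 0.30),
                       signature_mix_branch = c(S6 = 0.45, S15 = 0.45, S1 = 0.10),
                       purity_range = c(0.2, 0.9),
                       mean_depth = 200L,
                       normal_depth = 100L,
                       genome = NULL,
                       catalog = NULL,
                       cna_events = NULL,
                       loss_events = NULL,
                       panel_size = 14L,
                       artifact_rate = 0.02,
                       artifact_prevalence = 0.3,
                       error_rate = 0.001,
                       normal_contamination = 0,
                       min_clone_ccf = 0.3,
                       depth_override = NULL,
                       clone_regions = NULL,
                       clone_ccf = NULL) {
  genome <- genome %||% toy_genome(seed = child_seed(seed, 1L))
  catalog <- catalog %||% synthetic_signature_catalog()
  regions_all <- c(sprintf("R%d", seq_len(n_regions)),
                   if (n_lymph_nodes > 0L)
                     sprintf("LN%d", seq_len(n_lymph_nodes)))
  if (is.null(clone_tree)) {
    ## draw random trees until one admits a spatial occupancy over the
    ## available regions (deep chains may not fit few regions)
    for (k in 0:49) {
      clone_tree <- random_clone_tree(n_clones, mut_range,
                                      seed = child_seed(seed, 2L) + k)
      occ_try <- tryCatch(
        assign_clone_regions(clone_tree, regions_all,
                             seed = child_seed(seed, 3L) + k),
        error = function(e) NULL)
      if (!is.null(occ_try)) {
        if (is.null(clone_regions)) clone_regions <- occ_try
        break
      }
      clone_tree <- NULL
    }
    if (is.null(clone_tree)) {
      stop_mseq("could not draw a clone tree fitting %d regions",
                length(regions_all))
    }
  }
  cfg <- structure(list(
    seed = as.integer(seed), n_regions = as.integer(n_regions),
    n_lymph_nodes = as.integer(n_lymph_nodes), clone_tree = clone_tree,
    truncal_mutations = as.integer(truncal_mutations),
    indel_fraction = indel_fraction,
    signature_mix_trunk = normalise_mix(signature_mix_trunk),
    signature_mix_branch = normalise_mix(signature_mix_branch),
    purity_range = purity_range, mean_depth = mean_depth,
    normal_depth = normal_depth, genome = genome, catalog = catalog,
    cna_events = cna_events, loss_events = loss_events,
    panel_size = as.integer(panel_size), artifact_rate = artifact_rate,
    artifact_prevalence = artifact_prevalence, error_rate = error_rate,
    normal_contamination = normal_contamination,
    min_clone_ccf = min_clone_ccf, depth_override = depth_override,
    clone_regions = clone_regions, clone_ccf = clone_ccf
  ), class = "mseq_sim_config")
  validate_sim_config(cfg)
  cfg
}

normalise_mix <- function(mix) {
  if (any(mix < 0)) stop_mseq("signature mixture weights must be nonnegative")
  if (sum(mix) <= 0) stop_mseq("signature mixture weights must not all be zero")
  mix / sum(mix)
}

validate_sim_config <- function(cfg) {
  tr <- cfg$clone_tree
  if (!all(c("clone", "parent", "n_mutations") %in% names(tr))) {
    stop_mseq("clone_tree needs columns clone, parent, n_mutations")
  }
  roots <- tr$clone[tr$parent == 0L]
  if (length(roots) != 1L) {
    stop_mseq("clone_tree must have exactly one root (parent = 0)")
  }
  if (!all(tr$parent %in% c(0L, tr$clone))) {
    stop_mseq("clone_tree parent ids must reference clones")
  }
  ## rootedness: every clone reaches the root
  for (cl in tr$clone) {
    seen <- integer(0); v <- cl
    while (v != 0L) {
      if (v %in% seen) stop_mseq("clone_tree contains a cycle")
      seen <- c(seen, v)
      v <- tr$parent[match(v, tr$clone)]
    }
  }
  if (cfg$purity_range[1] <= 0 || cfg$purity_range[2] > 1 ||
      cfg$purity_range[1] > cfg$purity_range[2]) {
    stop_mseq("purity_range must lie within (0, 1]")
  }
  if (cfg$indel_fraction < 0 || cfg$indel_fraction > 1) {
    stop_mseq("indel_fraction must be in [0, 1]")
  }
  if (cfg$artifact_rate < 0 || cfg$artifact_rate > 1) {
    stop_mseq("artifact_rate must be in [0, 1]")
  }
  mixes <- c(names(cfg$signature_mix_trunk), names(cfg$signature_mix_branch))
  if (!all(mixes %in% colnames(cfg$catalog))) {
    stop_mseq("signature mixture references unknown signature id")
  }
  if (!is.null(cfg$cna_events)) {
    ev <- cfg$cna_events
    if (any(ev$cn_major < ev$cn_minor) || any(ev$cn_minor < 0)) {
      stop_mseq("cna_events require cn_major >= cn_minor >= 0")
    }
    if (any(ev$cn_major < 1)) stop_mseq("cna_events require cn_major >= 1")
    if (anyDuplicated(ev$chrom)) {
      stop_mseq("at most one cna_event per chromosome")
    }
    if (!all(ev$timing %in% c("before_mutations", "after_mutations"))) {
      stop_mseq("cna_events timing must be before_mutations/after_mutations")
    }
    if (!all(ev$clone %in% tr$clone)) stop_mseq("cna_events reference unknown clone")
  }
  if (!is.null(cfg$loss_events)) {
    if (!all(cfg$loss_events$clone %in% tr$clone)) {
      stop_mseq("loss_events reference unknown clone")
    }
    if (!is.null(cfg$cna_events) &&
        any(cfg$loss_events$chrom %in% cfg$cna_events$chrom)) {
      stop_mseq("loss_events and cna_events may not target the same chromosome")
    }
  }
  if (!is.null(cfg$clone_ccf)) {
    check_sum_rule(cfg$clone_ccf, tr)
  }
  invisible(cfg)
}

## Lineage sum rule: a parent's CCF must cover the sum of its children's
## CCFs in every region.
check_sum_rule <- function(clone_ccf, tree, tol = 1e-9) {
  for (cl in tree$clone) {
    kids <- tree$clone[tree$parent == cl]
    if (!length(kids)) next
    kid_sum <- colSums(clone_ccf[as.character(kids), , drop = FALSE])
    if (any(kid_sum > clone_ccf[as.character(cl), ] + tol)) {
      stop_mseq("clone CCFs violate the lineage sum rule at clone %s", cl)
    }
  }
  invisible(TRUE)
}

#' Generate a random rooted clone tree
#'
#' @param n_clones total number of clones including the truncal root.
#' @param mut_range integer range for per-branch mutation counts.
#' @param seed RNG seed.
#' @return data.frame with `clone`, `parent` (0 for the root), `n_mutations`.
#' @export
random_clone_tree <- function(n_clones, mut_range = c(150L, 400L), seed = 1L,
                              max_depth = 3L) {
  stopifnot(n_clones >= 1L)
  with_seed(seed, {
    ## branched rather than chain-like topologies (multi-region tumour trees
    ## are typically shallow): parents are drawn among nodes above max_depth
    depth <- 0L
    parent <- integer(n_clones)
    for (i in seq_len(n_clones)[-1]) {
      cand <- which(depth[seq_len(i - 1L)] < max_depth)
      p <- if (length(cand) == 1L) cand else sample(cand, 1L)
      parent[i] <- p
      depth[i] <- depth[p] + 1L
    }
    nm <- c(0L, sample(seq(mut_range[1], mut_range[2]), n_clones - 1L,
                       replace = TRUE))
    data.frame(clone = seq_len(n_clones), parent = parent, n_mutations = nm)
  })
}

ancestors_of <- function(tree, clone) {
  out <- integer(0)
  v <- tree$parent[match(clone, tree$clone)]
  while (v != 0L) {
    out <- c(out, v)
    v <- tree$parent[match(v, tree$clone)]
  }
  out
}

subtree_of <- function(tree, clone) {
  out <- clone
  frontier <- clone
  while (length(frontier)) {
    kids <- tree$clone[tree$parent %in% frontier]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

## Spatial occupancy: the root occupies all regions; each internal node's
## children receive disjoint, nonempty, strict subsets of the parent's
## regions. This encodes spatial locality (sibling lineages segregate into
## different regions) and guarantees that region sets nest exactly along
## ancestor-descendant lines.
assign_clone_regions <- function(tree, regions, seed, max_tries = 200L) {
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      occ <- list()
      occ[[as.character(tree$clone[tree$parent == 0L])]] <- regions
      ok <- TRUE
      for (v in tree$clone) {
        kids <- tree$clone[tree$parent == v]
        if (!length(kids)) next
        avail <- occ[[as.character(v)]]
        reserve <- if (length(kids) == 1L) 1L else 0L
        if (length(avail) - reserve < length(kids)) { ok <- FALSE; break }
        pool <- sample(avail)
        budget <- length(pool) - reserve
        sizes <- rep(1L, length(kids))
        spare <- budget - length(kids)
        while (spare > 0L) {
          i <- sample.int(length(kids), 1L)
          if (stats::runif(1) < 0.6) sizes[i] <- sizes[i] + 1L
          spare <- spare - 1L
        }
        offs <- cumsum(c(0L, sizes[-length(sizes)]))
        for (j in seq_along(kids)) {
          occ[[as.character(kids[j])]] <- pool[(offs[j] + 1L):(offs[j] + sizes[j])]
        }
      }
      if (ok) return(occ)
    }
    stop_mseq("could not assign clone regions; tree too deep for region count")
  })
}

## Per-region clone CCFs: the clones present in a region form a root-to-tip
## path (a consequence of disjoint sibling occupancy), so CCFs along the path
## only need to be decreasing with a floor at min_clone_ccf.
draw_clone_ccf <- function(tree, occ, regions, min_ccf, seed) {
  clones <- tree$clone
  C <- matrix(0, nrow = length(clones), ncol = length(regions),
              dimnames = list(as.character(clones), regions))
  depth <- vapply(clones, function(cl) length(ancestors_of(tree, cl)),
                  integer(1))
  with_seed(seed, {
    for (r in regions) {
      path <- clones[vapply(clones, function(cl) {
        r %in% occ[[as.character(cl)]]
      }, logical(1))]
      path <- path[order(depth[match(path, clones)])]
      k <- length(path) - 1L
      C[as.character(path[1]), r] <- 1
      if (k > 0L) {
        hi <- 0.92
        base <- if (k == 1L) stats::runif(1, min_ccf + 0.15, hi)
                else seq(hi, max(min_ccf, hi - 0.18 * (k - 1L)), length.out = k)
        vals <- base + stats::runif(k, -0.04, 0.04)
        vals <- clamp(sort(vals, decreasing = TRUE), min_ccf, 0.95)
        ## enforce strict decrease
        for (i in seq_len(k)[-1]) {
          vals[i] <- min(vals[i], vals[i - 1L] - 0.02)
        }
        vals <- clamp(vals, min_ccf, 0.95)
        C[as.character(path[-1]), r] <- vals
      }
    }
    C
  })
}

#' Sample trinucleotide-context substitutions from a signature mixture
#'
#' Draws `n` substitution categories from the mixture distribution
#' `catalog %*% mix` over the 96 contexts. The empirical spectrum converges
#' to the mixture as `n` grows.
#'
#' @param signature_mix named weights over catalog columns (normalised).
#' @param catalog 96 x S probability matrix.
#' @param n number of draws.
#' @param seed RNG seed.
#' @return character vector of `n` context labels.
#' @export
sample_contexts <- function(signature_mix, catalog, n, seed = 1L) {
  signature_mix <- normalise_mix(signature_mix)
  if (!all(names(signature_mix) %in% colnames(catalog))) {
    stop_mseq("signature mixture references unknown signature id")
  }
  if (n == 0L) return(character(0))
  probs <- as.vector(catalog[, names(signature_mix), drop = FALSE] %*%
                       signature_mix)
  with_seed(seed, {
    sample(rownames(catalog), n, replace = TRUE, prob = probs)
  })
}

#' Simulate a ground-truthed multi-region tumour dataset
#'
#' Generates the full input bundle the analysis pipeline consumes: a
#' multi-sample variant table with per-region and matched-normal allele
#' counts, per-region allele-specific copy-number segment profiles with
#' purities, and a ground-truth object recording the clone tree, clone
#' mixtures, per-mutation multiplicities, expected VAFs, copy-loss deletions
#' and gain-timing labels.
#'
#' Observed alt counts follow `Binomial(depth, expected VAF)` with
#' `depth ~ Poisson(mean_depth)` and
#' `expected VAF = p * m * CCF / (p * CN_total + 2 * (1 - p))`,
#' where `p` is region purity, `m` the mutation multiplicity and `CN_total`
#' the locus total copy number in that region. Mutations deleted by loss
#' events have expected VAF 0 in the affected regions. Output is
#' deterministic given the config seed.
#'
#' @param config an [sim_config()] object.
#' @return list with `sites` (data.frame), `segments` (list of
#'   [segment_profile()] objects, one per region) and `truth`
#'   (class `mseq_truth`).
#' @export
simulate_tumour <- function(config) {
  stopifnot(inherits(config, "mseq_sim_config"))
  cfg <- config
  tr <- cfg$clone_tree
  root <- tr$clone[tr$parent == 0L]
  tr$n_mutations[tr$clone == root] <- cfg$truncal_mutations
  regions <- c(sprintf("R%d", seq_len(cfg$n_regions)),
               if (cfg$n_lymph_nodes > 0L)
                 sprintf("LN%d", seq_len(cfg$n_lymph_nodes)))

  occ <- cfg$clone_regions %||%
    assign_clone_regions(tr, regions, seed = child_seed(cfg$seed, 3L))
  C <- cfg$clone_ccf %||%
    draw_clone_ccf(tr, occ, regions, cfg$min_clone_ccf,
                   seed = child_seed(cfg$seed, 4L))
  check_sum_rule(C, tr)
  purity <- with_seed(child_seed(cfg$seed, 5L), {
    stats::setNames(stats::runif(length(regions), cfg$purity_range[1],
                                 cfg$purity_range[2]), regions)
  })

  muts <- draw_mutations(cfg, tr, root)
  n_mut <- nrow(muts)

  ## allele indicators used by gain duplication and loss deletion
  muts$on_flagged_allele <- with_seed(child_seed(cfg$seed, 6L), {
    stats::runif(n_mut) < 0.5
  })

  cn <- region_copy_number(cfg, tr, C, regions)
  M <- multiplicity_matrix(cfg, tr, C, muts, regions, root)
  lost <- attr(M, "lost")

  ## expected VAF per (mutation, region)
  ccf_mut <- C[as.character(muts$clone), , drop = FALSE]
  cn_tot <- matrix(2, nrow = n_mut, ncol = length(regions),
                   dimnames = list(muts$mutation_id, regions))
  for (r in regions) {
    seg <- cn[[r]]
    cn_tot[, r] <- seg$cn_total[match(muts$chrom, seg$chrom)]
  }
  pmat <- matrix(purity[regions], nrow = n_mut, ncol = length(regions),
                 byrow = TRUE)
  expected_vaf <- pmat * M * ccf_mut / (pmat * cn_tot + 2 * (1 - pmat))
  dimnames(expected_vaf) <- list(muts$mutation_id, regions)

  ## artifact sites: recurrent technical calls present in tumour reads
  n_art <- round_half_up(cfg$artifact_rate * n_mut)
  art <- draw_artifacts(cfg, n_art, muts)

  sites <- assemble_sites(cfg, muts, art, expected_vaf, regions)

  truth <- structure(list(
    tree = tr, regions = regions, clone_regions = occ, clone_ccf = C,
    purity = purity, mutations = muts, multiplicity = M,
    expected_vaf = expected_vaf, region_cn = cn,
    gain_timing = gain_timing_truth(cfg),
    lost_mutations = lost,
    artifact_sites = art$site_id %||% character(0),
    categories = truth_categories(muts, M, C, regions)
  ), class = "mseq_truth")

  segments <- lapply(regions, function(r) {
    segment_profile(r, purity[[r]], cn[[r]])
  })
  names(segments) <- regions

  list(sites = sites, segments = segments, truth = truth)
}

## Draw mutation identities: clones, kinds, contexts, genome positions and
## coding consequences.
draw_mutations <- function(cfg, tr, root) {
  genome <- cfg$genome
  idx <- context_position_index(genome)
  counts <- stats::setNames(tr$n_mutations, as.character(tr$clone))
  n_total <- sum(counts)
  clone_of <- rep(tr$clone, tr$n_mutations)

  with_seed(child_seed(cfg$seed, 7L), {
    is_indel <- stats::runif(n_total) < cfg$indel_fraction
  })

  ## contexts for SNVs, per clone compartment
  ctx <- character(n_total)
  snv_trunk <- which(!is_indel & clone_of == root)
  snv_branch <- which(!is_indel & clone_of != root)
  ctx[snv_trunk] <- sample_contexts(cfg$signature_mix_trunk, cfg$catalog,
                                    length(snv_trunk),
                                    seed = child_seed(cfg$seed, 8L))
  ctx[snv_branch] <- sample_contexts(cfg$signature_mix_branch, cfg$catalog,
                                     length(snv_branch),
                                     seed = child_seed(cfg$seed, 9L))

  with_seed(child_seed(cfg$seed, 10L), {
    chrom <- character(n_total); pos <- integer(n_total)
    ref <- character(n_total); alt <- character(n_total)
    used <- new.env(parent = emptyenv())
    parsed <- parse_context96(ctx[!is_indel])
    snv_i <- which(!is_indel)
    ## sample positions per trinucleotide class, without replacement
    for (tn in unique(parsed$trinuc)) {
      rows <- snv_i[parsed$trinuc == tn]
      pool <- idx[[tn]]
      if (is.null(pool) || nrow(pool) < length(rows)) {
        stop_mseq("toy genome too small for requested mutation count (context %s)", tn)
      }
      pick <- pool[sample.int(nrow(pool), length(rows)), , drop = FALSE]
      sel <- match(rows, snv_i)
      chrom[rows] <- pick$chrom
      pos[rows] <- pick$pos
      want_ref <- parsed$ref[sel]; want_alt <- parsed$alt[sel]
      flip <- pick$flip
      ref[rows] <- ifelse(flip, chartr("CT", "GA", want_ref), want_ref)
      alt[rows] <- ifelse(flip, chartr("ACGT", "TGCA", want_alt), want_alt)
    }
    ## resolve duplicate positions by resampling within class
    key <- paste(chrom, pos)
    dup <- which(!is_indel & duplicated(key))
    guard <- 0L
    while (length(dup) && guard < 50L) {
      for (i in dup) {
        tn <- parse_context96(ctx[i])$trinuc
        pool <- idx[[tn]]
        pick <- pool[sample.int(nrow(pool), 1L), , drop = FALSE]
        chrom[i] <- pick$chrom; pos[i] <- pick$pos
        p1 <- parse_context96(ctx[i])
        ref[i] <- if (pick$flip) chartr("CT", "GA", p1$ref) else p1$ref
        alt[i] <- if (pick$flip) chartr("ACGT", "TGCA", p1$alt) else p1$alt
      }
      key <- paste(chrom, pos)
      dup <- which(!is_indel & duplicated(key))
      guard <- guard + 1L
    }
    ## indels: context-free events at unused interior positions
    ind_i <- which(is_indel)
    if (length(ind_i)) {
      ch_len <- nchar(genome$seq)
      ind_ch <- sample(names(genome$seq), length(ind_i), replace = TRUE)
      ind_pos <- vapply(ind_ch, function(cc) {
        sample(2:(ch_len[[cc]] - 2L), 1L)
      }, integer(1))
      chrom[ind_i] <- ind_ch; pos[ind_i] <- ind_pos
      del <- stats::runif(length(ind_i)) < 0.5
      rb <- ref_base(genome, ind_ch, ind_pos)
      nb <- substring(genome$seq[ind_ch], ind_pos + 1L, ind_pos + 1L)
      ref[ind_i] <- ifelse(del, paste0(rb, nb), rb)
      alt[ind_i] <- ifelse(del, rb, paste0(rb, sample(BASES, length(ind_i),
                                                      replace = TRUE)))
    }
    muts <- data.frame(
      mutation_id = sprintf("M%04d", seq_len(n_total)),
      clone = clone_of,
      kind = ifelse(is_indel, "indel", "snv"),
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      context96 = ifelse(is_indel, NA_character_, ctx),
      stringsAsFactors = FALSE
    )
    muts$gene <- gene_at(genome, muts$chrom, muts$pos)
    ann <- annotate_consequence(genome, muts)
    muts$consequence <- ann$consequence
    muts$protein_change <- ann$protein_change
    muts
  })
}

## Coding consequence from the in-frame gene tiling.
annotate_consequence <- function(genome, muts) {
  gl <- genome$gene_length
  n <- nrow(muts)
  consequence <- character(n); protein_change <- character(n)
  code <- Biostrings::GENETIC_CODE
  gstart <- ((muts$pos - 1L) %/% gl) * gl + 1L
  off <- (muts$pos - gstart) %% 3L
  codon_start <- muts$pos - off
  codon <- substring(genome$seq[muts$chrom], codon_start, codon_start + 2L)
  residue <- (muts$pos - gstart) %/% 3L + 1L
  aa_ref <- unname(code[codon])
  aa_ref[is.na(aa_ref)] <- "X"
  for (i in seq_len(n)) {
    if (muts$kind[i] == "indel") {
      consequence[i] <- "frameshift"
      protein_change[i] <- sprintf("%s%dfs", aa_ref[i], residue[i])
    } else {
      alt_codon <- codon[i]
      substr(alt_codon, off[i] + 1L, off[i] + 1L) <- muts$alt[i]
      aa_alt <- unname(code[alt_codon])
      if (is.na(aa_alt)) aa_alt <- "X"
      consequence[i] <- if (aa_alt == aa_ref[i]) "synonymous"
                        else if (aa_alt == "*") "stop_gained"
                        else if (aa_ref[i] == "*") "stop_lost"
                        else "missense"
      protein_change[i] <- sprintf("%s%d%s", aa_ref[i], residue[i], aa_alt)
    }
  }
  list(consequence = consequence, protein_change = protein_change)
}

## Integer copy-number state and unrounded total per region x chromosome.
## CNA and loss events are regionally clonal: they apply where the carrying
## clone's CCF exceeds 0.5, i.e. where it dominates the cancer cell
## population of the region.
region_copy_number <- function(cfg, tr, C, regions) {
  chroms <- names(cfg$genome$seq)
  lens <- nchar(cfg$genome$seq)
  out <- list()
  for (r in regions) {
    seg <- data.frame(chrom = chroms, start = 1L, end = unname(lens),
                      cn_total = 2, cn_major = 1L, cn_minor = 1L,
                      stringsAsFactors = FALSE)
    if (!is.null(cfg$cna_events)) {
      for (i in seq_len(nrow(cfg$cna_events))) {
        ev <- cfg$cna_events[i, ]
        if (C[as.character(ev$clone), r] > 0.5) {
          j <- match(as.character(ev$chrom), seg$chrom)
          seg$cn_major[j] <- ev$cn_major
          seg$cn_minor[j] <- ev$cn_minor
          seg$cn_total[j] <- ev$cn_major + ev$cn_minor
        }
      }
    }
    if (!is.null(cfg$loss_events)) {
      for (i in seq_len(nrow(cfg$loss_events))) {
        ev <- cfg$loss_events[i, ]
        if (C[as.character(ev$clone), r] > 0.5) {
          j <- match(as.character(ev$chrom), seg$chrom)
          seg$cn_major[j] <- 1L
          seg$cn_minor[j] <- 0L
          seg$cn_total[j] <- 1
        }
      }
    }
    out[[r]] <- seg
  }
  out
}

## Per (mutation, region) multiplicity; 0 marks a deletion by a loss event.
multiplicity_matrix <- function(cfg, tr, C, muts, regions, root) {
  n <- nrow(muts)
  M <- matrix(1L, nrow = n, ncol = length(regions),
              dimnames = list(muts$mutation_id, regions))
  lost <- data.frame(mutation_id = character(0), region = character(0),
                     stringsAsFactors = FALSE)
  if (!is.null(cfg$cna_events)) {
    for (i in seq_len(nrow(cfg$cna_events))) {
      ev <- cfg$cna_events[i, ]
      if (ev$cn_major < 2L) next
      pre_clones <- if (ev$timing == "after_mutations") {
        c(ancestors_of(tr, ev$clone), ev$clone)
      } else {
        ancestors_of(tr, ev$clone)
      }
      sel <- muts$chrom == as.character(ev$chrom) &
        muts$clone %in% pre_clones & muts$on_flagged_allele
      if (!any(sel)) next
      dom <- regions[C[as.character(ev$clone), regions] > 0.5]
      M[sel, dom] <- as.integer(ev$cn_major)
    }
  }
  if (!is.null(cfg$loss_events)) {
    for (i in seq_len(nrow(cfg$loss_events))) {
      ev <- cfg$loss_events[i, ]
      anc <- ancestors_of(tr, ev$clone)
      sel <- which(muts$chrom == as.character(ev$chrom) &
                     muts$clone %in% anc & muts$on_flagged_allele)
      if (!length(sel)) next
      dom <- regions[C[as.character(ev$clone), regions] > 0.5]
      for (r in dom) {
        M[sel, r] <- 0L
        lost <- rbind(lost, data.frame(mutation_id = muts$mutation_id[sel],
                                       region = r, stringsAsFactors = FALSE))
      }
    }
  }
  attr(M, "lost") <- lost
  M
}

gain_timing_truth <- function(cfg) {
  if (is.null(cfg$cna_events)) {
    return(data.frame(clone = integer(0), chrom = character(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  ev <- cfg$cna_events
  data.frame(clone = ev$clone, chrom = as.character(ev$chrom),
             label = ifelse(ev$timing == "before_mutations", "early", "late"),
             stringsAsFactors = FALSE)
}

## Noiseless presence (clone present and multiplicity > 0) and the
## ubiquitous/shared/private partition implied by it.
truth_categories <- function(muts, M, C, regions) {
  pres <- (C[as.character(muts$clone), regions, drop = FALSE] > 0) & (M > 0L)
  npres <- rowSums(pres)
  cat <- ifelse(npres == length(regions), "ubiquitous",
                ifelse(npres == 1L, "private", "shared"))
  cat[npres == 0L] <- "lost_everywhere"
  data.frame(mutation_id = muts$mutation_id, category = cat,
             n_present = npres, stringsAsFactors = FALSE)
}

draw_artifacts <- function(cfg, n_art, muts) {
  if (n_art == 0L) {
    return(data.frame(site_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE))
  }
  genome <- cfg$genome
  with_seed(child_seed(cfg$seed, 11L), {
    used <- paste(muts$chrom, muts$pos)
    ch_len <- nchar(genome$seq)
    ch <- sample(names(genome$seq), n_art, replace = TRUE)
    pos <- vapply(ch, function(cc) sample(2:(ch_len[[cc]] - 1L), 1L),
                  integer(1))
    keep <- !(paste(ch, pos) %in% used)
    ch <- ch[keep]; pos <- pos[keep]
    rb <- ref_base(genome, ch, pos)
    ab <- vapply(rb, function(b) sample(setdiff(BASES, b), 1L), character(1))
    data.frame(site_id = sprintf("ART%03d", seq_along(ch)), chrom = ch,
               pos = pos, ref = rb, alt = unname(ab),
               stringsAsFactors = FALSE)
  })
}

## Render the site table with observed allele counts.
assemble_sites <- function(cfg, muts, art, expected_vaf, regions) {
  n_mut <- nrow(muts); n_art <- nrow(art)
  noiseless <- !is.null(cfg$depth_override) && is.infinite(cfg$depth_override)
  base_depth <- if (noiseless) 1e6 else cfg$mean_depth
  sites <- data.frame(
    site_id = c(muts$mutation_id, art$site_id),
    chrom = c(muts$chrom, art$chrom),
    pos = c(muts$pos, art$pos),
    ref = c(muts$ref, art$ref),
    alt = c(muts$alt, art$alt),
    kind = c(muts$kind, rep("snv", n_art)),
    gene = c(muts$gene, rep(NA_character_, n_art)),
    consequence = c(muts$consequence, rep("missense", n_art)),
    protein_change = c(muts$protein_change, rep(NA_character_, n_art)),
    stringsAsFactors = FALSE
  )
  with_seed(child_seed(cfg$seed, 12L), {
    for (r in regions) {
      ev <- c(expected_vaf[, r], if (n_art) stats::runif(n_art, 0.04, 0.15))
      if (noiseless) {
        depth <- rep(base_depth, n_mut + n_art)
        alt_n <- round(ev * depth)
      } else {
        depth <- stats::rpois(n_mut + n_art, cfg$mean_depth)
        p <- clamp(ev + cfg$error_rate * (1 - ev), 0, 1)
        alt_n <- stats::rbinom(n_mut + n_art, depth, p)
      }
      sites[[paste0(r, "_depth")]] <- as.integer(depth)
      sites[[paste0(r, "_alt")]] <- as.integer(alt_n)
    }
    if (noiseless) {
      nd <- rep(as.integer(1e6), n_mut + n_art)
      na_ <- rep(0L, n_mut + n_art)
    } else {
      nd <- stats::rpois(n_mut + n_art, cfg$normal_depth)
      mean_vaf <- rowMeans(expected_vaf)
      pn <- clamp(c(cfg$normal_contamination * mean_vaf, rep(0, n_art)) +
                    cfg$error_rate, 0, 1)
      na_ <- stats::rbinom(n_mut + n_art, nd, pn)
    }
    sites$normal_depth <- as.integer(nd)
    sites$normal_alt <- as.integer(na_)
    sites
  })
}

#' Simulate a panel of unmatched normal samples
#'
#' Produces per-site VAFs for `panel_size` normal samples. A chosen subset of
#' sites (the simulator's artifact sites, or an explicit `artifact_sites`
#' vector) shows a VAF >= 2% in an expected `prevalence` fraction of the
#' normals, mimicking recurrent alignment artifacts; all other sites carry
#' only sequencing-error-level signal.
#'
#' @param config an [sim_config()].
#' @param sites site table from [simulate_tumour()] (defines the loci).
#' @param artifact_sites site ids to treat as recurrent artifacts; defaults
#'   to the simulator's artifact sites (ids starting `ART`).
#' @param prevalence per-normal carrier probability for artifact sites.
#' @return numeric matrix (sites x normals) of VAFs, with attribute
#'   `artifact_sites`.
#' @export
simulate_normal_panel <- function(config, sites,
                                  artifact_sites = NULL,
                                  prevalence = config$artifact_prevalence) {
  stopifnot(inherits(config, "mseq_sim_config"))
  artifact_sites <- artifact_sites %||%
    sites$site_id[startsWith(sites$site_id, "ART")]
  n <- nrow(sites); k <- config$panel_size
  with_seed(child_seed(config$seed, 13L), {
    depth <- matrix(stats::rpois(n * k, config$normal_depth), n, k)
    alt <- matrix(stats::rbinom(n * k, as.vector(depth), config$error_rate),
                  n, k)
    ## background error support is capped at a single read: recurrent
    ## multi-read support at a site is exactly what the artifact mechanism
    ## models, so non-artifact sites stay below the 2% carrier threshold
    alt <- pmin(alt, 1L)
    vaf <- alt / pmax(depth, 60L)
    is_art <- sites$site_id %in% artifact_sites
    if (any(is_art)) {
      for (i in which(is_art)) {
        carrier <- stats::runif(k) < prevalence
        vaf[i, carrier] <- stats::runif(sum(carrier), 0.02, 0.10)
      }
    }
    dimnames(vaf) <- list(sites$site_id, sprintf("N%02d", seq_len(k)))
    attr(vaf, "artifact_sites") <- artifact_sites
    vaf
  })
}
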