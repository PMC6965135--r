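## Shared fixtures and independent oracles used across test files.

## Minimal site table builder: vafs is a regions-column matrix of VAFs,
## rendered at a fixed depth.
make_sites <- function(vafs, depth = 200L, chrom = "1",
                       normal_depth = 100L, normal_alt = 0L,
                       consequence = "missense") {
  n <- nrow(vafs)
  df <- data.frame(
    site_id = sprintf("S%03d", seq_len(n)),
    chrom = rep(chrom, length.out = n),
    pos = seq(100L, by = 100L, length.out = n),
    ref = "C", alt = "T", kind = "snv",
    gene = NA_character_, consequence = consequence,
    protein_change = NA_character_,
    stringsAsFactors = FALSE
  )
  for (j in seq_len(ncol(vafs))) {
    r <- colnames(vafs)[j]
    df[[paste0(r, "_depth")]] <- depth
    df[[paste0(r, "_alt")]] <- as.integer(round(vafs[, j] * depth))
  }
  df$normal_depth <- normal_depth
  df$normal_alt <- normal_alt
  df
}

## Minimal diploid segment profile covering one long segment per chromosome.
flat_profile <- function(region, purity = 1, chroms = "1", len = 1e6,
                         cn_major = 1L, cn_minor = 1L) {
  segment_profile(region, purity, data.frame(
    chrom = chroms, start = 1L, end = as.integer(len),
    cn_total = cn_major + cn_minor, cn_major = cn_major, cn_minor = cn_minor,
    stringsAsFactors = FALSE))
}

## Hand-constructed mseq_ccf object from a CCF matrix (NA = absent).
make_ccf <- function(ccf_mat, consequence = "missense",
                     category = NULL) {
  pres <- !is.na(ccf_mat)
  sites <- data.frame(
    site_id = rownames(ccf_mat), chrom = "1",
    pos = seq(100L, by = 100L, length.out = nrow(ccf_mat)),
    ref = "C", alt = "T", kind = "snv", gene = NA_character_,
    consequence = rep(consequence, length.out = nrow(ccf_mat)),
    protein_change = NA_character_, stringsAsFactors = FALSE)
  category <- category %||% mseqevo:::presence_category(pres)
  structure(list(sites = sites, vaf = ccf_mat / 2, mut_cn = ccf_mat,
                 m = (ccf_mat * 0) + 1L, ccf = ccf_mat, ccf_raw = ccf_mat,
                 presence = pres, category = category),
            class = "mseq_ccf")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Hand-built cluster set with explicit patterns and centroids.
make_clusters <- function(centroids, patterns, sizes = NULL) {
  n <- nrow(centroids)
  sizes <- sizes %||% rep(10L, n)
  cl <- lapply(seq_len(n), function(i) {
    list(id = i,
         members = sprintf("C%d_M%03d", i, seq_len(sizes[i])),
         centroid = centroids[i, ],
         pattern = patterns[i, ])
  })
  structure(list(clusters = cl, unassigned = character(0),
                 regions = colnames(centroids)),
            class = "mseq_clusters")
}

## --- Independent brute-force filter oracle -------------------------------
## Reapplies every threshold site by site with plain loops; returns retained
## site ids with per-region presence and category.
brute_force_calls <- function(sites, panel,
                              min_region_depth = 70, min_germline_depth = 20,
                              max_germline_vaf = 0.02, max_germline_alt = 2,
                              pon_vaf = 0.02, pon_prev = 0.20,
                              tier1 = 0.05, tier2 = 0.025) {
  regions <- mseqevo::region_ids(sites)
  out <- list()
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    if (s$chrom %in% c("X", "Y", "chrX", "chrY")) next
    depths <- vapply(regions, function(r) s[[paste0(r, "_depth")]], numeric(1))
    if (any(depths < min_region_depth)) next
    if (s$normal_depth < min_germline_depth) next
    gvaf <- if (s$normal_depth > 0) s$normal_alt / s$normal_depth else 0
    if (gvaf > max_germline_vaf && s$normal_alt > max_germline_alt) next
    if (s$site_id %in% rownames(panel)) {
      carriers <- 0
      pv <- panel[s$site_id, ]
      for (v in pv) if (v >= pon_vaf) carriers <- carriers + 1
      if (carriers / length(pv) >= pon_prev) next
    }
    vafs <- vapply(regions, function(r) {
      d <- s[[paste0(r, "_depth")]]
      if (d > 0) s[[paste0(r, "_alt")]] / d else 0
    }, numeric(1))
    if (max(vafs) < tier1) next
    pres <- vafs > tier2
    np <- sum(pres)
    category <- if (np == length(regions)) "ubiquitous"
                else if (np == 1) "private"
                else if (np == 0) "absent" else "shared"
    out[[length(out) + 1L]] <- list(id = s$site_id, presence = pres,
                                    category = category)
  }
  out
}

## --- Independent exhaustive clone-tree oracle ----------------------------
## Enumerates every parent assignment (0 = root) by counting in mixed radix,
## applying the containment and acyclicity rules naively, and ranks by
## (error, specificity, lexicographic edge string).
oracle_best_tree <- function(clusters, epsilon = 0.1) {
  cl <- clusters$clusters
  n <- length(cl)
  centroids <- do.call(rbind, lapply(cl, function(x) x$centroid))
  patterns <- do.call(rbind, lapply(cl, function(x) x$pattern))
  ## naive candidate-parent lists (containment + centroid dominance)
  cand <- vector("list", n)
  for (i in seq_len(n)) {
    cand[[i]] <- 0L
    for (p in seq_len(n)) {
      if (p == i) next
      ok <- TRUE
      for (r in seq_len(ncol(patterns))) {
        if (patterns[i, r] && !patterns[p, r]) ok <- FALSE
        if (centroids[p, r] < centroids[i, r] - epsilon - 1e-9) ok <- FALSE
      }
      if (ok) cand[[i]] <- c(cand[[i]], p)
    }
  }
  best <- NULL
  score <- function(parent) {
    err <- 0; spec <- 0
    for (v in 0:n) {
      kids <- which(parent == v)
      if (length(kids)) {
        ks <- colSums(centroids[kids, , drop = FALSE])
        pc <- if (v == 0L) rep(1, ncol(centroids)) else centroids[v, ]
        err <- err + sum(pmax(0, ks - pc))
      }
    }
    for (i in seq_len(n)) {
      spec <- spec + if (parent[i] == 0L) ncol(centroids)
                     else sum(centroids[parent[i], ])
    }
    list(err = err, spec = spec, edges = paste(parent, collapse = ","))
  }
  acyclic <- function(parent) {
    for (i in seq_len(n)) {
      seen <- integer(0); v <- i
      while (v != 0L) {
        if (v %in% seen) return(FALSE)
        seen <- c(seen, v); v <- parent[v]
      }
    }
    TRUE
  }
  recurse <- function(parent, i) {
    if (i > n) {
      if (!acyclic(parent)) return()
      key <- score(parent)
      if (is.null(best) ||
          key$err < best$err - 1e-12 ||
          (abs(key$err - best$err) < 1e-12 && key$spec < best$spec - 1e-12) ||
          (abs(key$err - best$err) < 1e-12 &&
           abs(key$spec - best$spec) < 1e-12 && key$edges < best$edges)) {
        best <<- c(key, list(parent = parent))
      }
      return()
    }
    for (p in cand[[i]]) {
      parent[i] <- p
      recurse(parent, i + 1L)
    }
  }
  recurse(integer(n), 1L)
  best
}

## Map inferred clusters to true clones by majority membership; TRUE when
## every true ancestor-descendant clone pair is recovered in the tree.
topology_recovered <- function(tree, clusters, truth) {
  map <- vapply(clusters$clusters, function(x) {
    cls <- truth$mutations$clone[match(x$members,
                                       truth$mutations$mutation_id)]
    if (all(is.na(cls))) return(NA_integer_)
    as.integer(names(which.max(table(cls))))
  }, integer(1))
  if (anyNA(map)) return(FALSE)
  if (length(map) != nrow(truth$tree)) return(FALSE)
  if (length(unique(map)) != nrow(truth$tree)) return(FALSE)
  for (a in truth$tree$clone) {
    for (b in truth$tree$clone) {
      if (a == b) next
      true_anc <- a %in% mseqevo:::ancestors_of(truth$tree, b)
      inf_anc <- mseqevo:::is_ancestor(tree, which(map == a), which(map == b))
      if (true_anc != inf_anc) return(FALSE)
    }
  }
  TRUE
}

## Full filter chain used by several tests.
run_calls <- function(sim, cfg) {
  panel <- simulate_normal_panel(cfg, sim$sites)
  qf <- quality_filter(sim$sites)
  cg <- cross_germline_filter(qf$pass, panel)
  two_tier_call(cg$pass)
}
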