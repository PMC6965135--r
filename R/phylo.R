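#' Cluster mutations by regional CCF profiles
#'
#' Mutations are grouped first by their presence pattern (a mutation is
#' present in a region when its CCF there exceeds `present_min`, absent when
#' at or below `absent_max`), then split within a pattern by
#' average-linkage hierarchical clustering of the CCF vectors cut at
#' `cut_height`. Clusters smaller than `min_cluster` are dissolved into the
#' unassigned set, except that a small cluster containing a flagged driver
#' mutation may be retained (`retain_driver_clusters`), mirroring the manual
#' rescue of small driver-bearing subclones.
#'
#' @param ccf an `mseq_ccf` object or a numeric CCF matrix with absent
#'   entries equal to 0 or NA.
#' @param min_cluster minimum cluster size.
#' @param absent_max CCF at or below which a mutation is absent.
#' @param present_min CCF above which a mutation is present.
#' @param cut_height dendrogram cut height for within-pattern splitting
#'   (Euclidean distance over region CCFs).
#' @param drivers optional character vector of driver mutation ids.
#' @param retain_driver_clusters keep small clusters that contain a driver.
#' @return object of class `mseq_clusters`: list with `clusters` (list of
#'   id, members, centroid, pattern), `unassigned` (mutation ids), `regions`.
#' @export
cluster_ccfs <- function(ccf, min_cluster = 8L, absent_max = 0,
                         present_min = 1e-4, cut_height = 0.6,
                         drivers = character(0),
                         retain_driver_clusters = TRUE) {
  mat <- if (inherits(ccf, "mseq_ccf")) ccf$ccf else ccf
  if (is.null(dim(mat)) || nrow(mat) == 0L) stop_mseq("empty CCF matrix")
  mat[is.na(mat)] <- 0
  regions <- colnames(mat)
  pres <- mat > present_min
  pattern_key <- apply(pres, 1L, function(x) paste(as.integer(x), collapse = ""))
  groups <- split(rownames(mat), pattern_key)
  groups <- groups[order(names(groups), decreasing = TRUE)]

  clusters <- list(); unassigned <- character(0); cid <- 0L
  for (g in groups) {
    if (all(!pres[g[1], ])) { unassigned <- c(unassigned, g); next }
    sub <- mat[g, , drop = FALSE]
    memb <- if (length(g) == 1L) {
      stats::setNames(1L, g)
    } else {
      hc <- stats::hclust(stats::dist(sub), method = "average")
      stats::setNames(stats::cutree(hc, h = cut_height), g)
    }
    for (k in sort(unique(memb))) {
      ids <- names(memb)[memb == k]
      keep <- length(ids) >= min_cluster ||
        (retain_driver_clusters && any(ids %in% drivers))
      if (!keep) { unassigned <- c(unassigned, ids); next }
      cid <- cid + 1L
      clusters[[cid]] <- list(
        id = cid,
        members = ids,
        centroid = colMeans(mat[ids, , drop = FALSE]),
        pattern = pres[ids[1], ]
      )
    }
  }
  ## deterministic ids: order clusters by size desc, then centroid sum desc
  ord <- order(-vapply(clusters, function(cl) length(cl$members), numeric(1)),
               -vapply(clusters, function(cl) sum(cl$centroid), numeric(1)))
  clusters <- clusters[ord]
  for (i in seq_along(clusters)) clusters[[i]]$id <- i
  structure(list(clusters = clusters, unassigned = unassigned,
                 regions = regions),
            class = "mseq_clusters")
}

#' @export
print.mseq_clusters <- function(x, ...) {
  cat(sprintf("%d clusters, %d unassigned mutations\n",
              length(x$clusters), length(x$unassigned)))
  for (cl in x$clusters) {
    cat(sprintf("  #%d: %d mutations, present in %s\n", cl$id,
                length(cl$members),
                paste(x$regions[cl$pattern], collapse = ",")))
  }
  invisible(x)
}

## Tree error score: per region and node, the amount by which the children's
## summed CCF centroids exceed the parent's.
tree_error_score <- function(parent, centroids) {
  err <- 0
  for (v in unique(parent)) {
    kids <- which(parent == v)
    if (!length(kids)) next
    kid_sum <- colSums(centroids[kids, , drop = FALSE])
    par_c <- if (v == 0L) rep(1, ncol(centroids)) else centroids[v, ]
    err <- err + sum(pmax(0, kid_sum - par_c))
  }
  err
}

## Secondary ranking term: total CCF mass of each node's parent; smaller
## means each node hangs from its most specific compatible ancestor.
tree_specificity <- function(parent, centroids) {
  sum(vapply(seq_along(parent), function(i) {
    v <- parent[i]
    if (v == 0L) ncol(centroids) else sum(centroids[v, ])
  }, numeric(1)))
}

parent_is_tree <- function(parent) {
  n <- length(parent)
  for (i in seq_len(n)) {
    seen <- logical(n); v <- i
    while (v != 0L) {
      if (seen[v]) return(FALSE)
      seen[v] <- TRUE
      v <- parent[v]
    }
  }
  TRUE
}

max_violation <- function(parent, centroids) {
  worst <- 0
  for (v in unique(parent)) {
    kids <- which(parent == v)
    if (!length(kids)) next
    kid_sum <- colSums(centroids[kids, , drop = FALSE])
    par_c <- if (v == 0L) rep(1, ncol(centroids)) else centroids[v, ]
    worst <- max(worst, max(kid_sum - par_c))
  }
  worst
}

#' Build a clone tree from CCF clusters
#'
#' Reconstructs the lineage tree over mutation clusters under two
#' constraints: (a) containment -- a cluster can only descend from a cluster
#' whose presence regions include its own (the germline root is present
#' everywhere); (b) the lineage sum rule within slack `epsilon` per region --
#' a parent's CCF centroid must cover the sum of its children's. The error
#' score of a candidate tree is the total sum-rule excess over all regions
#' and nodes. Trees are ranked by error score; ties are resolved by
#' preferring the most specific valid parent for each node (smallest parent
#' CCF mass), then by lexicographic edge list. The search is exhaustive for
#' up to `max_exhaustive` clusters and greedy with single-edge local search
#' beyond. If no tree satisfies the slack constraint the best-effort tree is
#' returned flagged invalid.
#'
#' @param clusters an `mseq_clusters` object.
#' @param epsilon per-region sum-rule slack.
#' @param max_exhaustive exhaustive-search size limit.
#' @param n_top number of ranked trees to return.
#' @return object of class `mseq_tree`: list with `parent` (integer vector
#'   over cluster ids; 0 = germline root), `clusters`, `error_score`,
#'   `valid`, `ranked` (list of alternative parent vectors with scores).
#' @export
build_tree <- function(clusters, epsilon = 0.1, max_exhaustive = 12L,
                       n_top = 5L) {
  stopifnot(inherits(clusters, "mseq_clusters"))
  cl <- clusters$clusters
  n <- length(cl)
  if (n == 0L) stop_mseq("no clusters to build a tree from")
  centroids <- do.call(rbind, lapply(cl, function(x) x$centroid))
  patterns <- do.call(rbind, lapply(cl, function(x) x$pattern))

  ## candidate parents by containment (0 = germline root, present everywhere)
  candidates <- lapply(seq_len(n), function(i) {
    cand <- 0L
    for (j in seq_len(n)) {
      if (j == i) next
      if (all(patterns[j, ] | !patterns[i, ]) &&
          all(centroids[j, ] >= centroids[i, ] - epsilon - 1e-9)) {
        cand <- c(cand, j)
      }
    }
    cand
  })

  n_comb <- prod(vapply(candidates, length, numeric(1)))
  if (n <= max_exhaustive && n_comb <= 2e5) {
    sol <- search_exhaustive(candidates, centroids)
  } else {
    sol <- search_greedy(candidates, centroids)
  }
  best <- sol$ranked[[1]]
  structure(list(
    parent = best$parent,
    clusters = clusters,
    centroids = centroids,
    error_score = best$error,
    valid = max_violation(best$parent, centroids) <= epsilon + 1e-9,
    ranked = sol$ranked[seq_len(min(n_top, length(sol$ranked)))]
  ), class = "mseq_tree")
}

rank_key <- function(parent, centroids) {
  c(tree_error_score(parent, centroids),
    tree_specificity(parent, centroids))
}

search_exhaustive <- function(candidates, centroids) {
  grid <- expand.grid(candidates, KEEP.OUT.ATTRS = FALSE)
  sols <- list()
  for (i in seq_len(nrow(grid))) {
    parent <- as.integer(grid[i, ])
    if (!parent_is_tree(parent)) next
    key <- rank_key(parent, centroids)
    sols[[length(sols) + 1L]] <- list(parent = parent, error = key[1],
                                      spec = key[2],
                                      edges = paste(parent, collapse = ","))
  }
  if (!length(sols)) stop_mseq("no tree satisfies the containment constraints")
  ## round ranking keys so that float noise cannot break genuine ties
  ord <- order(round(vapply(sols, `[[`, numeric(1), "error"), 9L),
               round(vapply(sols, `[[`, numeric(1), "spec"), 9L),
               vapply(sols, `[[`, character(1), "edges"))
  list(ranked = sols[ord])
}

search_greedy <- function(candidates, centroids, max_iter = 200L) {
  n <- length(candidates)
  ## start: most specific candidate parent for each node
  parent <- vapply(seq_len(n), function(i) {
    cand <- candidates[[i]]
    mass <- vapply(cand, function(v) {
      if (v == 0L) ncol(centroids) + 1 else sum(centroids[v, ])
    }, numeric(1))
    cand[order(mass)][1]
  }, integer(1))
  if (!parent_is_tree(parent)) parent <- rep(0L, n)
  best_key <- rank_key(parent, centroids)
  for (iter in seq_len(max_iter)) {
    improved <- FALSE
    for (i in seq_len(n)) {
      for (v in candidates[[i]]) {
        if (v == parent[i]) next
        trial <- parent; trial[i] <- v
        if (!parent_is_tree(trial)) next
        key <- rank_key(trial, centroids)
        if (key[1] < best_key[1] - 1e-12 ||
            (abs(key[1] - best_key[1]) < 1e-12 && key[2] < best_key[2] - 1e-12)) {
          parent <- trial; best_key <- key; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(ranked = list(list(parent = parent, error = best_key[1],
                          spec = best_key[2],
                          edges = paste(parent, collapse = ","))))
}

#' @export
print.mseq_tree <- function(x, ...) {
  cat(sprintf("Clone tree: %d clusters, error score %.4g%s\n",
              length(x$parent), x$error_score,
              if (x$valid) "" else " (INVALID: sum-rule slack exceeded)"))
  for (i in seq_along(x$parent)) {
    cat(sprintf("  %s -> #%d (%d mutations)\n",
                if (x$parent[i] == 0L) "germline" else sprintf("#%d", x$parent[i]),
                i, length(x$clusters$clusters[[i]]$members)))
  }
  invisible(x)
}

## Ancestor test within an mseq_tree (strict).
is_ancestor <- function(tree, a, b) {
  v <- tree$parent[b]
  while (v != 0L) {
    if (v == a) return(TRUE)
    v <- tree$parent[v]
  }
  FALSE
}

#' Explain presence-pattern conflicts by copy loss
#'
#' A mutation conflicts with the tree when it is absent from a region where
#' its clade is present. Because mutations deleted by a regional copy loss
#' drop out of the clusters formed from their observed presence pattern,
#' each mutation is first matched to its *home clade*: the most specific
#' cluster whose presence regions strictly contain the mutation's and whose
#' CCF centroid lies within `match_tol` of the mutation's CCF in every
#' region where the mutation is present. Regions where the home clade is
#' present but the mutation absent are conflicts; a conflict is
#' `explained_by_loss` when the locus total copy number in that region is
#' lower than in every region where the mutation is present, `unexplained`
#' when copy number is flat, and `uncovered` when the locus lies outside
#' segment coverage.
#'
#' @param ccf an `mseq_ccf` object.
#' @param tree an `mseq_tree`.
#' @param segments named list of [segment_profile()] objects.
#' @param match_tol maximum per-region CCF distance between a mutation and
#'   its home clade centroid.
#' @return data.frame with one row per conflicting (mutation, region):
#'   `mutation_id`, `region`, `status`
#'   (`explained_by_loss`/`unexplained`/`uncovered`).
#' @export
explain_conflicts <- function(ccf, tree, segments, match_tol = 0.25) {
  regions <- colnames(ccf$presence)
  clusters <- tree$clusters$clusters
  patterns <- do.call(rbind, lapply(clusters, function(x) x$pattern))
  centroids <- do.call(rbind, lapply(clusters, function(x) x$centroid))
  out <- list()
  for (mid in rownames(ccf$presence)) {
    pres <- ccf$presence[mid, ]
    if (!any(pres)) next
    v <- ccf$ccf[mid, ]
    ## candidate home clades: strict pattern supersets with matching CCFs
    cand <- which(vapply(seq_len(nrow(patterns)), function(j) {
      all(patterns[j, ] | !pres) && any(patterns[j, ] & !pres) &&
        max(abs(centroids[j, pres] - v[pres])) <= match_tol
    }, logical(1)))
    if (!length(cand)) next
    home <- cand[order(rowSums(patterns[cand, , drop = FALSE]),
                       vapply(cand, function(j) {
                         max(abs(centroids[j, pres] - v[pres]))
                       }, numeric(1)))][1]
    conf <- regions[patterns[home, ] & !pres]
    site <- ccf$sites[ccf$sites$site_id == mid, ]
    cn_pres <- vapply(regions[pres], function(r) {
      locus_cn(segments[[r]], site$chrom, site$pos)
    }, numeric(1))
    for (r in conf) {
      cn_r <- locus_cn(segments[[r]], site$chrom, site$pos)
      status <- if (is.na(cn_r) || all(is.na(cn_pres))) {
        "uncovered"
      } else if (cn_r < min(cn_pres, na.rm = TRUE)) {
        "explained_by_loss"
      } else {
        "unexplained"
      }
      out[[length(out) + 1L]] <- data.frame(
        mutation_id = mid, region = r, home_cluster = home, status = status,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(mutation_id = character(0), region = character(0),
                      home_cluster = integer(0), status = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

locus_cn <- function(profile, chrom, pos) {
  i <- segment_at(profile, chrom, pos)
  if (is.na(i)) return(NA_real_)
  seg <- profile$segments[i, ]
  seg$cn_major + seg$cn_minor
}

cluster_of_mutation <- function(clusters) {
  out <- character(0)
  for (cl in clusters$clusters) {
    out[cl$members] <- as.character(cl$id)
  }
  out
}

#' Detect parallel evolution of driver mutations
#'
#' Emits an event when driver-flagged mutations in the same gene map to at
#' least two distinct branches that are not in an ancestor-descendant
#' relation (parallel acquisition), or to the trunk plus a branch
#' (progressive inactivation, type `trunk_branch`). The `same_residue` flag
#' marks events where two branches carry an identical protein change or
#' changes at hotspot-proximal residues (within `hotspot_window` residues).
#'
#' @param tree an `mseq_tree`.
#' @param annotation data.frame with `site_id` (or `mutation_id`), `gene`,
#'   `protein_change` and `likely_driver` columns (see [classify_driver()]).
#' @param hotspot_window residue distance treated as hotspot-proximal.
#' @return data.frame with `gene`, `type` (`parallel`/`trunk_branch`),
#'   `n_branches`, `branches`, `same_residue`.
#' @export
detect_parallel_evolution <- function(tree, annotation, hotspot_window = 3L) {
  id_col <- if ("site_id" %in% names(annotation)) "site_id" else "mutation_id"
  cl_of <- cluster_of_mutation(tree$clusters)
  drv <- annotation[annotation$likely_driver %in% TRUE, , drop = FALSE]
  drv$cluster <- unname(cl_of[drv[[id_col]]])
  drv <- drv[!is.na(drv$cluster) & !is.na(drv$gene), , drop = FALSE]
  if (!nrow(drv)) {
    return(data.frame(gene = character(0), type = character(0),
                      n_branches = integer(0), branches = character(0),
                      same_residue = logical(0), stringsAsFactors = FALSE))
  }
  ## trunk = clusters present in all regions hanging off the germline root
  all_pres <- vapply(tree$clusters$clusters,
                     function(cl) all(cl$pattern), logical(1))
  trunk_ids <- which(all_pres & tree$parent == 0L)
  out <- list()
  for (g in unique(drv$gene)) {
    dg <- drv[drv$gene == g, ]
    nodes <- sort(unique(as.integer(dg$cluster)))
    if (length(nodes) < 2L) next
    is_trunk <- nodes %in% trunk_ids
    branch_nodes <- nodes[!is_trunk]
    ## pairwise ancestral relations among branch nodes
    non_anc_pair <- FALSE
    if (length(branch_nodes) >= 2L) {
      for (a in seq_along(branch_nodes)) {
        for (b in seq_along(branch_nodes)) {
          if (a >= b) next
          x <- branch_nodes[a]; y <- branch_nodes[b]
          if (!is_ancestor(tree, x, y) && !is_ancestor(tree, y, x)) {
            non_anc_pair <- TRUE
          }
        }
      }
    }
    type <- if (non_anc_pair) "parallel"
            else if (any(is_trunk) && length(branch_nodes) >= 1L) "trunk_branch"
            else NA_character_
    if (is.na(type)) next
    pc <- dg$protein_change[!is.na(dg$protein_change)]
    same_res <- any(duplicated(pc)) ||
      hotspot_proximal(pc, hotspot_window)
    out[[length(out) + 1L]] <- data.frame(
      gene = g, type = type, n_branches = length(nodes),
      branches = paste(nodes, collapse = ","), same_residue = same_res,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(gene = character(0), type = character(0),
                      n_branches = integer(0), branches = character(0),
                      same_residue = logical(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

hotspot_proximal <- function(protein_changes, window) {
  pos <- suppressWarnings(as.integer(gsub("[^0-9]", "", protein_changes)))
  pos <- pos[!is.na(pos)]
  if (length(pos) < 2L) return(FALSE)
  d <- abs(outer(pos, pos, "-"))
  any(d[upper.tri(d)] <= window)
}

#' Write a clone tree in Newick format
#'
#' Branch lengths are the number of mutations assigned to each cluster; the
#' tree is rooted at the germline.
#'
#' @param tree an `mseq_tree`.
#' @param path optional output file; when NULL the Newick string is returned.
#' @return the Newick string, invisibly when written to file.
#' @export
tree_newick <- function(tree, path = NULL) {
  n <- length(tree$parent)
  kids <- lapply(0:n, function(v) which(tree$parent == v))
  lens <- vapply(tree$clusters$clusters,
                 function(cl) length(cl$members), integer(1))
  rec <- function(v) {
    label <- if (v == 0L) "germline" else sprintf("C%d", v)
    bl <- if (v == 0L) 0L else lens[v]
    ch <- kids[[v + 1L]]
    if (!length(ch)) {
      sprintf("%s:%d", label, bl)
    } else {
      sprintf("(%s)%s:%d", paste(vapply(ch, rec, character(1)),
                                 collapse = ","), label, bl)
    }
  }
  nwk <- paste0(rec(0L), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
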