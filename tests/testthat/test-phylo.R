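test_that("clustering groups by presence pattern and dissolves small clusters", {
  regions <- c("R1", "R2", "R3")
  ccf <- rbind(
    matrix(1.0, nrow = 10, ncol = 3),                 # trunk pattern
    cbind(matrix(0.5, nrow = 9, ncol = 2), 0),        # regions 1-2 only
    cbind(matrix(0.4, nrow = 5, ncol = 1), 0, 0))     # too small
  colnames(ccf) <- regions
  rownames(ccf) <- sprintf("M%03d", seq_len(nrow(ccf)))
  cl <- cluster_ccfs(ccf, min_cluster = 8)
  expect_length(cl$clusters, 2L)
  expect_setequal(cl$unassigned, sprintf("M%03d", 20:24))

  ## a small cluster with a flagged driver is retained
  cl2 <- cluster_ccfs(ccf, min_cluster = 8, drivers = "M022")
  expect_length(cl2$clusters, 3L)
  cl3 <- cluster_ccfs(ccf, min_cluster = 8, drivers = "M022",
                      retain_driver_clusters = FALSE)
  expect_length(cl3$clusters, 2L)
  expect_error(cluster_ccfs(ccf[0, , drop = FALSE]), "empty")
})

test_that("tree building resolves the two-region sibling fixture", {
  centroids <- rbind(trunk = c(R1 = 1.0, R2 = 1.0),
                     A = c(0.6, 0.0), B = c(0.0, 0.7))
  patterns <- rbind(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE))
  colnames(patterns) <- colnames(centroids)
  cl <- make_clusters(centroids, patterns)
  tree <- build_tree(cl)
  expect_equal(tree$parent, c(0L, 1L, 1L))
  expect_equal(tree$error_score, 0)
  expect_true(tree$valid)
  oracle <- oracle_best_tree(cl)
  expect_equal(tree$parent, oracle$parent)
})

test_that("sum-rule excess is scored when siblings overshoot the trunk", {
  ## A and B have mutually non-nested presence so neither can nest: their
  ## joint CCF exceeds the trunk in region 1 by 0.1
  centroids <- rbind(trunk = c(R1 = 1.0, R2 = 1.0, R3 = 1.0),
                     A = c(0.6, 0.6, 0.0), B = c(0.5, 0.0, 0.5))
  patterns <- rbind(rep(TRUE, 3), c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE))
  colnames(patterns) <- colnames(centroids)
  cl <- make_clusters(centroids, patterns)
  tree <- build_tree(cl)
  expect_equal(tree$parent, c(0L, 1L, 1L))
  expect_equal(tree$error_score, 0.1, tolerance = 1e-12)
  expect_true(tree$valid)  # within the default slack of 0.1
  expect_equal(tree$parent, oracle_best_tree(cl)$parent)

  ## a single truncal cluster forms a star tree with error 0
  solo <- make_clusters(centroids[1, , drop = FALSE],
                        patterns[1, , drop = FALSE])
  st <- build_tree(solo)
  expect_equal(st$parent, 0L)
  expect_equal(st$error_score, 0)
})

test_that("nested clusters hang from their most specific compatible parent", {
  centroids <- rbind(trunk = c(R1 = 1.0, R2 = 1.0, R3 = 1.0),
                     A = c(0.7, 0.6, 0.0), B = c(0.3, 0.25, 0.0))
  patterns <- rbind(rep(TRUE, 3), c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
  colnames(patterns) <- colnames(centroids)
  tree <- build_tree(make_clusters(centroids, patterns))
  expect_equal(tree$parent, c(0L, 1L, 2L))  # B under A, not a sibling
})

test_that("build_tree equals the exhaustive oracle on random instances", {
  set.seed(404)
  for (i in 1:12) {
    n_reg <- sample(3:5, 1)
    n_cl <- sample(2:5, 1)
    regions <- paste0("R", seq_len(n_reg))
    patterns <- matrix(FALSE, n_cl, n_reg, dimnames = list(NULL, regions))
    patterns[1, ] <- TRUE
    if (n_cl > 1) {
      for (j in 2:n_cl) {
        patterns[j, sample(n_reg, sample(1:(n_reg - 1), 1))] <- TRUE
      }
    }
    centroids <- matrix(0, n_cl, n_reg, dimnames = list(NULL, regions))
    centroids[1, ] <- 1
    if (n_cl > 1) {
      for (j in 2:n_cl) {
        centroids[j, patterns[j, ]] <- round(runif(sum(patterns[j, ]),
                                                   0.2, 0.9), 2)
      }
    }
    cl <- make_clusters(centroids, patterns)
    got <- tryCatch(build_tree(cl), error = function(e) NULL)
    want <- oracle_best_tree(cl)
    if (is.null(got)) {
      expect_null(want)
    } else {
      expect_equal(got$parent, want$parent)
      expect_equal(got$error_score, want$err, tolerance = 1e-12)
    }
  }
})

test_that("branch lengths conserve the assigned mutation count", {
  cfg <- sim_config(seed = 23, n_clones = 5, truncal_mutations = 200,
                    mut_range = c(40, 90), purity_range = c(0.5, 0.9))
  sim <- simulate_tumour(cfg)
  ccf <- compute_ccf(run_calls(sim, cfg), sim$segments)
  cl <- cluster_ccfs(ccf)
  tree <- build_tree(cl)
  assigned <- sum(vapply(cl$clusters, function(x) length(x$members),
                         integer(1)))
  expect_equal(assigned + length(cl$unassigned), nrow(ccf$presence))
  nwk <- tree_newick(tree)
  ph <- ape::read.tree(text = nwk)
  expect_equal(sum(ph$edge.length), assigned)
})

test_that("simulated topologies are recovered from noisy data", {
  ok <- vapply(1:10, function(i) {
    cfg <- sim_config(seed = 500 + i, n_regions = 7,
                      n_clones = 4 + (i %% 5), truncal_mutations = 300,
                      mut_range = c(60, 200), purity_range = c(0.5, 0.9))
    sim <- simulate_tumour(cfg)
    ccf <- compute_ccf(run_calls(sim, cfg), sim$segments)
    cl <- cluster_ccfs(ccf)
    topology_recovered(build_tree(cl), cl, sim$truth)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("copy-loss conflicts are explained and flat profiles are not", {
  cfg <- sim_config(seed = 5, n_clones = 4, truncal_mutations = 300,
                    mut_range = c(60, 120), depth_override = Inf,
                    error_rate = 0,
                    loss_events = data.frame(clone = 2L, chrom = "3"))
  sim <- simulate_tumour(cfg)
  ccf <- compute_ccf(run_calls(sim, cfg), sim$segments)
  tree <- build_tree(cluster_ccfs(ccf))
  conf <- explain_conflicts(ccf, tree, sim$segments)
  lost <- sim$truth$lost_mutations
  expect_gt(nrow(lost), 0)
  key_lost <- paste(lost$mutation_id, lost$region)
  key_expl <- paste(conf$mutation_id, conf$region)[
    conf$status == "explained_by_loss"]
  expect_true(all(key_lost %in% key_expl))
  expect_equal(sort(key_expl), sort(key_lost))  # and nothing else

  ## same tumour without the loss event: no loss explanations at all
  cfg0 <- sim_config(seed = 5, n_clones = 4, truncal_mutations = 300,
                     mut_range = c(60, 120), depth_override = Inf,
                     error_rate = 0)
  sim0 <- simulate_tumour(cfg0)
  ccf0 <- compute_ccf(run_calls(sim0, cfg0), sim0$segments)
  conf0 <- explain_conflicts(ccf0, build_tree(cluster_ccfs(ccf0)),
                             sim0$segments)
  expect_equal(sum(conf0$status == "explained_by_loss"), 0L)
})

test_that("parallel evolution events distinguish sibling and trunk patterns", {
  centroids <- rbind(trunk = c(R1 = 1, R2 = 1), A = c(0.6, 0), B = c(0, 0.7))
  patterns <- rbind(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE))
  colnames(patterns) <- colnames(centroids)
  cl <- make_clusters(centroids, patterns, sizes = c(3L, 3L, 3L))
  tree <- build_tree(cl)
  ids <- function(k, i) sprintf("C%d_M%03d", k, i)
  ann <- data.frame(
    site_id = c(ids(2, 1), ids(3, 1),   # same gene on sibling branches
                ids(1, 1), ids(2, 2),   # trunk + branch
                ids(1, 2),              # trunk only
                ids(2, 3), ids(3, 2)),  # same residue on siblings
    gene = c("SMARCA4", "SMARCA4", "ARID1A", "ARID1A", "RNF43",
             "PIK3CA", "PIK3CA"),
    protein_change = c("Q100fs", "T800fs", "M274fs", "K1071fs", "G659fs",
                       "H1047R", "H1047R"),
    likely_driver = TRUE, stringsAsFactors = FALSE)
  ev <- detect_parallel_evolution(tree, ann)
  expect_setequal(ev$gene, c("SMARCA4", "ARID1A", "PIK3CA"))
  expect_equal(ev$type[ev$gene == "SMARCA4"], "parallel")
  expect_equal(ev$type[ev$gene == "ARID1A"], "trunk_branch")
  expect_true(ev$same_residue[ev$gene == "PIK3CA"])
  expect_false("RNF43" %in% ev$gene)  # trunk-only gene emits no event
})
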