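test_that("expected VAF reaches its analytic limit for pure diploid clonal mutations", {
  tree <- data.frame(clone = 1L, parent = 0L, n_mutations = 50L)
  cfg <- sim_config(seed = 1, n_regions = 3, clone_tree = tree,
                    truncal_mutations = 50, indel_fraction = 0,
                    purity_range = c(1, 1), depth_override = Inf,
                    error_rate = 0, artifact_rate = 0)
  sim <- simulate_tumour(cfg)
  ## purity 1, CCF 1, diploid, multiplicity 1 -> VAF exactly 0.5
  for (r in c("R1", "R2", "R3")) {
    vaf <- sim$sites[[paste0(r, "_alt")]] / sim$sites[[paste0(r, "_depth")]]
    expect_equal(vaf, rep(0.5, nrow(sim$sites)))
  }
  expect_true(all(sim$truth$expected_vaf == 0.5))
})

test_that("the simulator is deterministic given the seed", {
  cfg <- sim_config(seed = 77, n_clones = 4, truncal_mutations = 120,
                    mut_range = c(40, 80))
  s1 <- simulate_tumour(cfg)
  s2 <- simulate_tumour(cfg)
  expect_identical(s1$sites, s2$sites)
  expect_identical(s1$truth$clone_ccf, s2$truth$clone_ccf)
  expect_identical(simulate_normal_panel(cfg, s1$sites),
                   simulate_normal_panel(cfg, s2$sites))
})

test_that("truth categories count truncal mutations as ubiquitous", {
  ## 700 truncal + 1200 branch mutations over 7 regions: before any loss
  ## event exactly the truncal mutations are ubiquitous
  tree <- data.frame(clone = 1:4, parent = c(0L, 1L, 1L, 2L),
                     n_mutations = c(0L, 500L, 400L, 300L))
  cfg <- sim_config(seed = 5, n_regions = 7, clone_tree = tree,
                    truncal_mutations = 700)
  sim <- simulate_tumour(cfg)
  cats <- sim$truth$categories
  expect_equal(sum(cats$category == "ubiquitous"), 700L)
  expect_equal(sum(cats$category %in% c("shared", "private")), 1200L)
})

test_that("generated clone fractions always obey the lineage sum rule", {
  for (sd in 1:8) {
    cfg <- sim_config(seed = sd, n_clones = 4 + (sd %% 4),
                      truncal_mutations = 50, mut_range = c(20, 40))
    sim <- simulate_tumour(cfg)
    expect_true(mseqevo:::check_sum_rule(sim$truth$clone_ccf,
                                         sim$truth$tree))
    ## root clone covers all cancer cells in every region
    root <- sim$truth$tree$clone[sim$truth$tree$parent == 0L]
    expect_true(all(sim$truth$clone_ccf[as.character(root), ] == 1))
  }
})

test_that("observed VAFs converge to the expected-VAF formula", {
  cfg <- sim_config(seed = 21, n_regions = 4, n_clones = 3,
                    truncal_mutations = 600, mut_range = c(100, 200),
                    purity_range = c(0.6, 0.9), mean_depth = 200,
                    error_rate = 0, artifact_rate = 0)
  sim <- simulate_tumour(cfg)
  ev <- sim$truth$expected_vaf
  ids <- sim$truth$mutations$mutation_id
  for (r in c("R1", "R2")) {
    obs <- sim$sites[[paste0(r, "_alt")]] / sim$sites[[paste0(r, "_depth")]]
    names(obs) <- sim$sites$site_id
    sel <- ids[ev[ids, r] > 0.05]
    delta <- mean(obs[sel]) - mean(ev[sel, r])
    se <- sqrt(mean(ev[sel, r] * (1 - ev[sel, r]) / 200) / length(sel))
    expect_lt(abs(delta), 3 * se)
  }
})

test_that("noiseless presence reproduces the truth categories", {
  cfg <- sim_config(seed = 31, n_clones = 5, truncal_mutations = 300,
                    mut_range = c(60, 120), depth_override = Inf,
                    error_rate = 0, purity_range = c(0.5, 0.9))
  sim <- simulate_tumour(cfg)
  pres <- run_calls(sim, cfg)
  truth_cat <- sim$truth$categories
  shared_ids <- intersect(names(pres$category), truth_cat$mutation_id)
  expect_gt(length(shared_ids), 0.95 * nrow(truth_cat))
  got <- pres$category[shared_ids]
  want <- truth_cat$category[match(shared_ids, truth_cat$mutation_id)]
  expect_equal(unname(got), want)
})

test_that("context sampling follows the signature mixture distribution", {
  cat96 <- synthetic_signature_catalog()
  ## pure signature: empirical spectrum within L1 0.02 of the column
  ctx <- sample_contexts(c(S3 = 1), cat96, 1e5, seed = 9)
  emp <- as.numeric(table(factor(ctx, levels = rownames(cat96)))) / 1e5
  expect_lt(sum(abs(emp - cat96[, "S3"])), 0.02)
  ## two-signature mixture
  ctx <- sample_contexts(c(S6 = 0.6, S15 = 0.4), cat96, 1e5, seed = 10)
  emp <- as.numeric(table(factor(ctx, levels = rownames(cat96)))) / 1e5
  expect_lt(sum(abs(emp - (0.6 * cat96[, "S6"] + 0.4 * cat96[, "S15"]))),
            0.02)
  expect_identical(sample_contexts(c(S1 = 1), cat96, 0), character(0))
  expect_error(sample_contexts(c(NOPE = 1), cat96, 10), "unknown signature")
})

test_that("normal panel carries artifacts at the configured prevalence", {
  cfg0 <- sim_config(seed = 2, truncal_mutations = 200, n_clones = 2,
                     mut_range = c(10, 20), artifact_rate = 0)
  sim0 <- simulate_tumour(cfg0)
  panel0 <- simulate_normal_panel(cfg0, sim0$sites)
  expect_true(all(panel0 < 0.02))

  cfg <- sim_config(seed = 3, truncal_mutations = 400, n_clones = 2,
                    mut_range = c(10, 20), artifact_rate = 0.25,
                    artifact_prevalence = 0.3, panel_size = 14)
  sim <- simulate_tumour(cfg)
  panel <- simulate_normal_panel(cfg, sim$sites)
  art <- attr(panel, "artifact_sites")
  expect_gt(length(art), 50)
  carriers <- rowSums(panel[art, , drop = FALSE] >= 0.02)
  ## binomial expectation: 0.3 * 14 = 4.2 carriers per artifact site
  expect_lt(abs(mean(carriers) - 4.2), 3 * sqrt(14 * 0.3 * 0.7 / length(art)))

  panel_full <- simulate_normal_panel(cfg, sim$sites, prevalence = 1)
  expect_true(all(panel_full[art, ] >= 0.02))
})

test_that("invalid configurations are rejected", {
  bad_tree <- data.frame(clone = 1:2, parent = c(0L, 0L),
                         n_mutations = c(10L, 10L))
  expect_error(sim_config(clone_tree = bad_tree), "exactly one root")
  cyc <- data.frame(clone = 1:3, parent = c(0L, 3L, 2L),
                    n_mutations = c(1L, 1L, 1L))
  expect_error(sim_config(clone_tree = cyc), "cycle")
  expect_error(sim_config(purity_range = c(0, 0.5)), "purity_range")
  expect_error(sim_config(cna_events = data.frame(
    clone = 1L, chrom = "1", cn_major = 1L, cn_minor = 2L,
    timing = "before_mutations")), "cn_major >= cn_minor")
  ## user-supplied clone CCFs violating the sum rule are rejected
  tree <- data.frame(clone = 1:3, parent = c(0L, 1L, 1L),
                     n_mutations = c(10L, 10L, 10L))
  ccf <- matrix(c(1, 0.7, 0.7), nrow = 3, ncol = 2,
                dimnames = list(1:3, c("R1", "R2")))
  expect_error(sim_config(clone_tree = tree, n_regions = 2,
                          clone_regions = list(`1` = c("R1", "R2"),
                                               `2` = "R1", `3` = "R2"),
                          clone_ccf = ccf), "sum rule")
})
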