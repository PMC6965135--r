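test_that("quality filter applies thresholds in documented order", {
  vafs <- matrix(0.2, nrow = 6, ncol = 2,
                 dimnames = list(NULL, c("R1", "R2")))
  sites <- make_sites(vafs, depth = 100L)
  sites$chrom[1] <- "X"                      # sex chromosome
  sites$R2_depth[2] <- 69L                   # tumour depth boundary
  sites$normal_depth[3] <- 19L               # germline depth boundary
  sites$normal_alt[4] <- 3L                  # vaf 0.03 AND count 3 -> reject
  sites$normal_alt[5] <- 2L                  # vaf 0.02, count 2 -> retain
  res <- quality_filter(sites)
  expect_setequal(res$pass$site_id, c("S005", "S006"))
  expect_equal(res$fail$reason[match(c("S001", "S002", "S003", "S004"),
                                     res$fail$site_id)],
               c("sex_chromosome", "tumour_depth", "germline_depth",
                 "germline_evidence"))
  ## sex-chromosome reason takes precedence over later failures
  sites$R1_depth[1] <- 10L
  expect_equal(quality_filter(sites)$fail$reason[1], "sex_chromosome")
})

test_that("germline evidence requires both VAF and count conditions", {
  vafs <- matrix(0.2, nrow = 4, ncol = 1, dimnames = list(NULL, "R1"))
  sites <- make_sites(vafs, depth = 100L, normal_depth = 100L)
  sites$normal_alt <- c(3L, 2L, 3L, 0L)
  sites$normal_depth <- c(100L, 66L, 200L, 100L)
  ## S1: vaf 0.03 & alt 3 -> reject; S2: vaf 0.0303 but alt 2 -> retain;
  ## S3: alt 3 but vaf 0.015 -> retain; S4: clean -> retain
  res <- quality_filter(sites)
  expect_setequal(res$pass$site_id, c("S002", "S003", "S004"))
  expect_equal(res$fail$reason, "germline_evidence")
})

test_that("panel filter rejects at 20% carrier prevalence", {
  vafs <- matrix(0.2, nrow = 3, ncol = 1, dimnames = list(NULL, "R1"))
  sites <- make_sites(vafs)
  panel <- matrix(0, nrow = 3, ncol = 14,
                  dimnames = list(sites$site_id, NULL))
  panel["S001", 1:3] <- 0.05   # 3/14 = 21.4% -> rejected
  panel["S002", 1:2] <- 0.05   # 2/14 = 14.3% -> retained
  res <- cross_germline_filter(sites, panel)
  expect_setequal(res$pass$site_id, c("S002", "S003"))
  expect_equal(res$fail$site_id, "S001")
  expect_error(cross_germline_filter(sites, NULL), "nonempty")
})

test_that("two-tier calling pins the stated threshold conventions", {
  vafs <- rbind(c(0.06, 0.01, 0.03),   # retained, presence 1,0,1 -> shared
                c(0.04, 0.04, 0.04),   # tier 1 fails
                c(0.30, 0.28, 0.26),   # ubiquitous
                c(0.05, 0.00, 0.00),   # tier 1 boundary: >= keeps it
                c(0.06, 0.025, 0.00))  # tier 2 boundary: strict > excludes
  colnames(vafs) <- c("R1", "R2", "R3")
  pres <- two_tier_call(make_sites(vafs, depth = 200L))
  expect_setequal(rownames(pres$presence), c("S001", "S003", "S004", "S005"))
  expect_equal(unname(pres$presence["S001", ]), c(TRUE, FALSE, TRUE))
  expect_equal(unname(pres$category["S001"]), "shared")
  expect_equal(unname(pres$category["S003"]), "ubiquitous")
  expect_equal(unname(pres$category["S004"]), "private")
  expect_equal(unname(pres$presence["S005", ]), c(TRUE, FALSE, FALSE))
  expect_true("S002" %in% pres$rejected)
})

test_that("raising the tier-2 threshold never increases presence counts", {
  cfg <- sim_config(seed = 17, n_clones = 4, truncal_mutations = 150,
                    mut_range = c(40, 80))
  sim <- simulate_tumour(cfg)
  qf <- quality_filter(sim$sites)
  thresholds <- c(0.01, 0.025, 0.05, 0.1)
  counts <- vapply(thresholds, function(t2) {
    sum(two_tier_call(qf$pass, tier2_vaf = t2)$presence)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("heterogeneity counts match a noiseless ground truth", {
  tree <- data.frame(clone = 1:3, parent = c(0L, 1L, 1L),
                     n_mutations = c(0L, 120L, 100L))
  cfg <- sim_config(seed = 41, n_regions = 5, clone_tree = tree,
                    truncal_mutations = 200, depth_override = Inf,
                    error_rate = 0, artifact_rate = 0)
  sim <- simulate_tumour(cfg)
  pres <- run_calls(sim, cfg)
  counts <- categorize_counts(pres)
  truth <- sim$truth
  nonsil <- truth$mutations$consequence != "synonymous"
  cats <- truth$categories$category[nonsil]
  expect_equal(counts$n_ubiquitous, sum(cats == "ubiquitous"))
  expect_equal(counts$n_heterogeneous, sum(cats %in% c("shared", "private")))
  expect_equal(counts$n_nonsilent, length(cats))
})

test_that("degenerate presence matrices summarise to zeros", {
  vafs <- matrix(0.3, nrow = 4, ncol = 3,
                 dimnames = list(NULL, c("R1", "R2", "R3")))
  pres <- two_tier_call(make_sites(vafs))
  counts <- categorize_counts(pres)
  expect_equal(counts$n_heterogeneous, 0L)
  expect_equal(counts$pct_ubiquitous, 100)

  empty <- two_tier_call(make_sites(vafs)[0, , drop = FALSE])
  expect_equal(categorize_counts(empty)$n_nonsilent, 0L)
})

test_that("driver classification fires the three stated rules", {
  ann <- data.frame(
    gene = c("KRAS", "B2M", "GENE999", "PIK3CA", "TP53"),
    consequence = c("missense", "frameshift", "missense", "missense",
                    "synonymous"),
    protein_change = c("G13D", "L20fs", "A100T", "H1047L", "R175R"),
    stringsAsFactors = FALSE)
  res <- classify_driver(ann)
  expect_equal(res$rule,
               c("known_change",      # KRAS G13D is catalogued
                 "disrupting_tsg",    # frameshift in a TSG
                 NA_character_,       # gene not in catalog
                 "hotspot_position",  # 1047 known, change differs
                 NA_character_))      # synonymous never a driver
  expect_equal(res$likely_driver, c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_error(classify_driver(data.frame(gene = "TP53",
                                          consequence = "weird",
                                          protein_change = "A1T")),
               "consequence vocabulary")
})
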