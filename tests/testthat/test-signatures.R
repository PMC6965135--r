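test_that("context counting works in the pyrimidine frame and conserves totals", {
  reference <- c(`1` = "AACATTGTA")
  ## C>T at positions 3 (ACA) and G>A at position 7 (TGT -> revcomp ACA)
  muts <- data.frame(chrom = "1", pos = c(3L, 7L), ref = c("C", "G"),
                     alt = c("T", "A"), kind = "snv",
                     stringsAsFactors = FALSE)
  sp <- count_contexts(muts, reference)
  expect_equal(unname(sp["A[C>T]A"]), 2)
  expect_equal(sum(sp), 2)

  ## edge loci are excluded and logged; totals conserve the rest
  muts2 <- data.frame(chrom = "1", pos = c(1L, 3L, 9L), ref = c("A", "C", "A"),
                      alt = c("T", "G", "C"), kind = "snv",
                      stringsAsFactors = FALSE)
  sp2 <- count_contexts(muts2, reference)
  expect_equal(sum(sp2), 1)
  expect_equal(nrow(attr(sp2, "excluded")), 2L)

  ## indels are skipped entirely
  muts3 <- rbind(muts, data.frame(chrom = "1", pos = 4L, ref = "AT",
                                  alt = "A", kind = "indel"))
  expect_equal(sum(count_contexts(muts3, reference)), 2)
  expect_error(count_contexts(data.frame(chrom = "9", pos = 2L, ref = "A",
                                         alt = "C", kind = "snv"),
                              reference), "cover")
})

test_that("simulated spectra agree with the truth contexts", {
  cfg <- sim_config(seed = 13, n_clones = 2, truncal_mutations = 400,
                    mut_range = c(50, 60), indel_fraction = 0.3,
                    artifact_rate = 0)
  sim <- simulate_tumour(cfg)
  sp <- count_contexts(sim$sites, cfg$genome)
  truth_ctx <- sim$truth$mutations$context96
  truth_ctx <- truth_ctx[!is.na(truth_ctx)]
  expect_equal(sum(sp), length(truth_ctx))
  tab <- table(factor(truth_ctx, levels = context96_labels()))
  expect_equal(as.numeric(sp), as.numeric(tab))
})

test_that("noiseless mixtures are recovered exactly by NNLS refitting", {
  cat96 <- synthetic_signature_catalog()
  ## exact catalog column
  w1 <- fit_signatures(cat96[, "S7"], cat96)
  expect_equal(unname(w1["S7"]), 1, tolerance = 1e-8)
  expect_lt(attr(w1, "residual"), 1e-10)
  ## convex mixture
  y <- 0.6 * cat96[, "S6"] + 0.4 * cat96[, "S15"]
  w2 <- fit_signatures(y, cat96)
  expect_equal(unname(w2[c("S6", "S15")]), c(0.6, 0.4), tolerance = 1e-6)
  expect_lt(max(w2[setdiff(names(w2), c("S6", "S15"))]), 1e-6)
  expect_error(fit_signatures(rep(0, 96), cat96), "all-zero")
})

test_that("sampled three-signature mixtures are recovered within 0.05", {
  cat96 <- synthetic_signature_catalog()
  truth <- c(S6 = 0.5, S15 = 0.3, S1 = 0.2)
  err <- t(vapply(1:30, function(i) {
    ctx <- sample_contexts(truth, cat96, 1000, seed = 100 + i)
    sp <- as.numeric(table(factor(ctx, levels = rownames(cat96))))
    w <- fit_signatures(sp, cat96)
    w[names(truth)] - truth
  }, numeric(3)))
  expect_lt(max(abs(colMeans(err))), 0.02)      # unbiased per weight
  expect_lt(mean(abs(err)), 0.05)               # accurate per replicate
})

test_that("adding a truly contributing signature never worsens the fit", {
  cat96 <- synthetic_signature_catalog()
  y <- 0.5 * cat96[, "S2"] + 0.3 * cat96[, "S9"] + 0.2 * cat96[, "S20"]
  res_without <- attr(fit_signatures(y, cat96[, c("S2", "S9")]), "residual")
  res_with <- attr(fit_signatures(y, cat96[, c("S2", "S9", "S20")]),
                   "residual")
  expect_lte(res_with, res_without + 1e-12)
  expect_lt(res_with, 1e-10)
})

test_that("reporting masks signatures below 5% in every group", {
  cat96 <- synthetic_signature_catalog()
  e1 <- fit_signatures(0.9 * cat96[, "S6"] + 0.1 * cat96[, "S1"], cat96)
  e2 <- fit_signatures(0.96 * cat96[, "S6"] + 0.04 * cat96[, "S1"], cat96)
  rep1 <- report_exposures(list(ubiquitous = e1, heterogeneous = e2))
  expect_true(all(c("S1", "S6") %in% rownames(rep1)))  # S1 >= 5% in group 1
  rep2 <- report_exposures(list(ubiquitous = e2, heterogeneous = e2))
  expect_false("S1" %in% rownames(rep2))               # below 5% everywhere
  expect_true("S6" %in% rownames(rep2))
})

test_that("trunk-to-branch signature shifts are recovered from groups", {
  cfg <- sim_config(seed = 29, n_clones = 4, truncal_mutations = 600,
                    mut_range = c(150, 250), indel_fraction = 0.2,
                    signature_mix_trunk = c(S6 = 0.3, S15 = 0.3, S1 = 0.4),
                    signature_mix_branch = c(S6 = 0.5, S15 = 0.4, S1 = 0.1),
                    purity_range = c(0.5, 0.9), artifact_rate = 0)
  sim <- simulate_tumour(cfg)
  pres <- run_calls(sim, cfg)
  grp <- ifelse(pres$category == "ubiquitous", "ubiquitous", "heterogeneous")
  snv <- pres$sites$kind == "snv"
  spectra <- spectra_by_group(pres$sites[snv, ], grp[snv], cfg$genome)
  expos <- lapply(spectra, fit_signatures, catalog = cfg$catalog)
  ## S1 enriched on the trunk, S6 enriched in the branches
  expect_gt(expos$ubiquitous["S1"], expos$heterogeneous["S1"] + 0.1)
  expect_gt(expos$heterogeneous["S6"], expos$ubiquitous["S6"] + 0.05)
})
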