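# Generators: planted-structure contracts, closed-form and resampling
# oracles, reproducibility, truth round-trips.

test_that("macrophage generator plants exact edges at zero noise", {
  tr <- macrophage_panel_truth("TF1", data.frame(tf = "TF1", target = "G1",
                                                 beta = 1),
                               noise_sd = 0, n_samples = 10)
  sim <- simulate_macrophage_expression(tr, seed = 1)
  expect_equal(unname(cor(sim$expr["TF1", ], sim$expr["G1", ])), 1,
               tolerance = 1e-12)
  expect_identical(dim(sim$expr), c(2L, 10L))
})

test_that("macrophage generator rejects bad truth and duplicate genes", {
  expect_error(macrophage_panel_truth("TF1",
    data.frame(tf = "TFX", target = "G1", beta = 1)), "TF endpoint")
  expect_error(macrophage_panel_truth("TF1",
    data.frame(tf = "TF1", target = "G1", beta = Inf)), "finite")
  expect_error(macrophage_panel_truth("TF1",
    data.frame(tf = "TF1", target = "G1", beta = 1), n_samples = 3), ">= 4")
  tr <- macrophage_panel_truth("TF1", data.frame(tf = "TF1", target = "G1",
                                                 beta = 1))
  tr$genes <- c(tr$genes, "G1")
  expect_error(simulate_macrophage_expression(tr, 1), "duplicate")
})

test_that("null co-expression matches the empirical null level at n = 38", {
  # oracle: mean |off-diagonal r| of independent Gaussians, 200 replicates
  oracle <- replicate(200, {
    r <- abs(cor(matrix(rnorm(30 * 38), ncol = 30)))
    mean(r[upper.tri(r)])
  })
  tr <- macrophage_panel_truth("TF1",
    data.frame(tf = character(), target = character(), beta = numeric()),
    n_samples = 38,
    background_genes = sprintf("B%02d", 1:29))
  gen <- vapply(1:200, function(s) {
    r <- abs(cor(t(simulate_macrophage_expression(tr, s)$expr)))
    mean(r[upper.tri(r)])
  }, numeric(1))
  expect_lt(abs(mean(gen) - mean(oracle)),
            3 * sd(oracle) / sqrt(200) + 3 * sd(gen) / sqrt(200))
})

test_that("edge correlation attenuates as 1/sqrt(1 + noise_sd^2)", {
  # closed form: corr(TF, beta*TF + e) = 1/sqrt(1 + sd^2) for beta = 1
  tr <- macrophage_panel_truth("TF1", data.frame(tf = "TF1", target = "G1",
                                                 beta = 1),
                               noise_sd = 0.5, n_samples = 38)
  rs <- vapply(1:100, function(s) {
    e <- simulate_macrophage_expression(tr, s)$expr
    cor(e["TF1", ], e["G1", ])
  }, numeric(1))
  expect_lt(abs(mean(rs) - 1 / sqrt(1.25)), 0.1)
})

test_that("timecourse nulls are exchangeable and truth is bookkept", {
  d0 <- timecourse_design(timepoints = "30", n_genes = 60,
    planted_pcl_genes = list("30" = data.frame(gene = "MG00001", lfc = 0)),
    planted_reactive_genes = list("30" = data.frame(gene = "MG00002",
                                                    lfc = 0)),
    noise_sd = 0.3)
  sim <- simulate_timecourse_expression(d0, seed = 4)
  ann <- sim$annotations
  # zero planted effect: the contrast means agree up to sampling noise
  ctrl <- ann$sample_id[ann$cell == "control"]
  post <- ann$sample_id[ann$cell == "post_pcl"]
  diffs <- rowMeans(sim$expr[, post]) - rowMeans(sim$expr[, ctrl])
  expect_lt(max(abs(diffs)), 5 * 0.3 * sqrt(1 / 6 + 1 / 6))
  expect_identical(sim$truth$planted_pcl_genes[["30"]]$gene, "MG00001")
  expect_identical(sim$truth$planted_reactive_genes[["30"]]$gene, "MG00002")
})

test_that("planted log2 effects land at their nominal size", {
  d <- timecourse_design(timepoints = "30", n_genes = 50,
    n_per_cell = c(control = 6, post_pcl = 6, regression_10wk = 6),
    planted_pcl_genes = list("30" = data.frame(gene = "MG00010", lfc = 2)),
    noise_sd = 0.1)
  diffs <- vapply(1:100, function(s) {
    sim <- simulate_timecourse_expression(d, s)
    ann <- sim$annotations
    mean(sim$expr["MG00010", ann$sample_id[ann$cell == "post_pcl"]]) -
      mean(sim$expr["MG00010", ann$sample_id[ann$cell == "control"]])
  }, numeric(1))
  expect_lt(abs(mean(diffs) - 2), 0.2)
})

test_that("timecourse design validates replicate counts", {
  expect_error(timecourse_design(n_per_cell = 2), ">= 3")
})

test_that("perfect-LD blocks give r-squared exactly 1", {
  tr <- make_genotype_truth(n_snps = 20, block = 4, block_r2 = 1)
  sim <- simulate_genotypes_gwas(tr, 60, seed = 2)
  r2 <- cor(t(sim$dosage[1:4, ]))^2
  expect_equal(unname(r2[upper.tri(r2)]), rep(1, 6), tolerance = 1e-12)
})

test_that("unplanted GWAS hits occur at the nominal 5% rate", {
  tr <- make_genotype_truth(n_snps = 1000, chrs = "1")
  hits <- vapply(1:30, function(s)
    mean(simulate_genotypes_gwas(tr, 60, seed = s)$gwas$p < 0.05),
    numeric(1))
  # binomial oracle: 30 x 1000 Bernoulli(0.05) draws
  expect_lt(abs(mean(hits) - 0.05), 3 * sqrt(0.05 * 0.95 / 30000))
})

test_that("planted cis effects are recovered by dosage regression", {
  tr <- make_genotype_truth(n_snps = 5, cis_effect = 1)
  slopes <- vapply(1:100, function(s) {
    sim <- simulate_genotypes_gwas(tr, 156, seed = s)
    unname(coef(lm(sim$expr["G1", ] ~ sim$dosage[1, ]))[2])
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 1), 0.15)
})

test_that("genotype truth validates its invariants", {
  st <- data.frame(snp = c("a", "b"), chr = "1", pos = c(2, 1), maf = 0.2)
  expect_error(genotype_truth(st), "strictly increasing")
  st$pos <- c(1, 2)
  st$maf <- c(0.2, 0.7)
  expect_error(genotype_truth(st), "MAF")
  st$maf <- 0.2
  expect_error(genotype_truth(st, list(list(snps = c("a", "b"), r2 = 1.5))),
               "r2")
  expect_error(simulate_genotypes_gwas(genotype_truth(st), 10, seed = 1),
               ">= 50")
})

test_that("knockdown screen reduces the target and shifts CE as planted", {
  tr <- perturbation_truth("TFX", knockdown_fraction = 0.8, ce_shift = 0.12)
  ratios <- vapply(1:30, function(s) {
    sim <- simulate_perturbation_screen(tr, 6, seed = s, noise_sd = 0.1)
    2^(mean(sim$knockdown["TFX", ]) - mean(sim$control["TFX", ]))
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.2), 0.02)
  ce <- vapply(1:50, function(s) {
    sim <- simulate_perturbation_screen(tr, 6, seed = s, ce_sd = 10)
    mean(sim$ce$ce[sim$ce$arm == "knockdown"]) -
      mean(sim$ce$ce[sim$ce$arm == "control"])
  }, numeric(1))
  expect_lt(abs(mean(ce) - 12), 10)
  # null shift centres at zero
  tr0 <- perturbation_truth("TFX", ce_shift = 0)
  ce0 <- vapply(1:50, function(s) {
    sim <- simulate_perturbation_screen(tr0, 6, seed = s, ce_sd = 10)
    mean(sim$ce$ce[sim$ce$arm == "knockdown"]) -
      mean(sim$ce$ce[sim$ce$arm == "control"])
  }, numeric(1))
  expect_lt(abs(mean(ce0)), 3 * 10 * sqrt(2 / 6) / sqrt(50))
  expect_error(simulate_perturbation_screen(tr, 2, seed = 1), ">= 3")
  expect_error(perturbation_truth("TFX", knockdown_fraction = 1), "\\(0, 1\\)")
  expect_error(perturbation_truth("TFX", panel_genes = c("a", "b")), "panel")
})

test_that("histology generator honours missingness and degenerate noise", {
  gm <- data.frame(group = c("a", "b"), sm22 = c(10, 20),
                   collagen = c(10, 15), cd68 = c(5, 2), oro = c(6, 3),
                   burden = c(4, 1))
  full <- simulate_histology(gm, group_sds = 0, n_mice = 6, seed = 1)
  expect_false(anyNA(full))
  # sds = 0: every mouse equals its group mean
  expect_equal(unique(full$sm22[full$group == "a"]), 10)
  expect_equal(unique(full$burden[full$group == "b"]), 1)
  # binomial oracle for the missing-cell count at the study's 16% rate
  nmiss <- vapply(1:50, function(s) {
    h <- simulate_histology(gm, group_sds = 1, n_mice = 12,
                            missing_rate = 0.16, seed = s)
    sum(is.na(h[, c("sm22", "collagen", "cd68", "oro", "burden")]))
  }, numeric(1))
  expect_lt(abs(mean(nmiss) - 0.16 * 120),
            3 * sqrt(120 * 0.16 * 0.84 / 50))
  expect_error(simulate_histology(gm, 1, 6, missing_rate = 1, seed = 1),
               "< 1")
  gm$sm22[1] <- 104
  expect_error(simulate_histology(gm, 1, 6, seed = 1), "\\[0, 100\\]")
})

test_that("all generators are bit-reproducible given (parameters, seed)", {
  tr <- make_panel_truth(n_tf = 3, per_tf = 2, extra = 5)
  expect_identical(simulate_macrophage_expression(tr, 7)$expr,
                   simulate_macrophage_expression(tr, 7)$expr)
  d <- timecourse_design(timepoints = "30", n_genes = 40)
  expect_identical(simulate_timecourse_expression(d, 7)$expr,
                   simulate_timecourse_expression(d, 7)$expr)
  gt <- make_genotype_truth(n_snps = 10, block = 3)
  a <- simulate_genotypes_gwas(gt, 60, seed = 7)
  b <- simulate_genotypes_gwas(gt, 60, seed = 7)
  expect_identical(a$dosage, b$dosage)
  expect_identical(a$gwas, b$gwas)
  pt <- perturbation_truth("TFX")
  expect_identical(simulate_perturbation_screen(pt, 4, seed = 7)$knockdown,
                   simulate_perturbation_screen(pt, 4, seed = 7)$knockdown)
  gm <- data.frame(group = "a", sm22 = 10, collagen = 10, cd68 = 5,
                   oro = 5, burden = 4)
  expect_identical(simulate_histology(gm, 1, 6, 0.2, seed = 7),
                   simulate_histology(gm, 1, 6, 0.2, seed = 7))
})

test_that("truth objects round-trip losslessly through JSON", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "t.json")

  tr <- make_panel_truth(n_tf = 2, per_tf = 2, extra = 3, noise_sd = 1 / 3)
  write_truth(tr, p)
  back <- read_truth(p)
  expect_equal(back$edge_list, tr$edge_list)
  expect_equal(back$noise_sd, tr$noise_sd)
  expect_setequal(back$genes, tr$genes)

  d <- timecourse_design(timepoints = c("30", "40"), n_genes = 25,
    planted_pcl_genes = list("30" = data.frame(gene = "MG00001", lfc = 1.5),
                             "40" = data.frame(gene = character(),
                                               lfc = numeric())),
    noise_sd = sqrt(2) / 10)
  write_truth(d, p)
  expect_equal(read_truth(p)$planted_pcl_genes, d$planted_pcl_genes)
  expect_equal(read_truth(p)$noise_sd, d$noise_sd)

  gt <- make_genotype_truth(n_snps = 6, block = 3, cis_effect = 0.7,
                            enriched = "rs1_001", p_hit = 0.1)
  write_truth(gt, p)
  back <- read_truth(p)
  expect_equal(back$snp_table, gt$snp_table)
  expect_equal(back$cis_effects, gt$cis_effects)
  expect_equal(back$p_hit, gt$p_hit)

  pt <- perturbation_truth("TFX", knockdown_fraction = 0.75,
                           ce_shift = -0.17)
  write_truth(pt, p)
  back <- read_truth(p)
  expect_identical(back$target_tf, pt$target_tf)
  expect_equal(back$knockdown_fraction, pt$knockdown_fraction)
  expect_equal(back$ce_shift, pt$ce_shift)
})
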