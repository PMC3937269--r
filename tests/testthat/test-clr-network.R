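# CLR similarity, background z-scores, edge significance, network
# thresholding, hub ranking.

# hand-built 4-gene similarity matrix used for frozen z arithmetic:
# row 1 off-diagonal {0.6, 0.3, 0.3}: mean 0.4, sd (0.6-0.3)/sqrt(3)
# row 2 off-diagonal {0.6, 0.7, 0.5}: mean 0.6 -> z contribution 0
# => z(1,2) = (0.6-0.4)/((0.3)/sqrt(3)) = 2/sqrt(3)
hand_sim <- function() {
  M <- matrix(c(NA, 0.6, 0.3, 0.3,
                0.6, NA, 0.7, 0.5,
                0.3, 0.7, NA, 0.2,
                0.3, 0.5, 0.2, NA), 4, 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  structure(list(M = M, genes = paste0("g", 1:4),
                 constant_genes = character()),
            class = "similarity_matrix")
}

test_that("similarity is |Pearson r| with flagged constant genes", {
  set.seed(1)
  x <- rnorm(20)
  expr <- rbind(a = x, dup = x, anti = -x, flat = rep(1, 20),
                noise = rnorm(20))
  colnames(expr) <- sprintf("s%02d", 1:20)
  sim <- compute_similarity(expr)
  expect_equal(sim$M["a", "dup"], 1, tolerance = 1e-12)
  expect_equal(sim$M["a", "anti"], 1, tolerance = 1e-12)  # sign folded
  expect_identical(sim$constant_genes, "flat")
  expect_equal(unname(sim$M["flat", c("a", "noise")]), c(0, 0))
  expect_true(all(is.na(diag(sim$M))))
  expect_error(compute_similarity(expr[, 1:3]), ">= 4")
  expect_error(compute_similarity(expr, "nope"), "nope")
})

test_that("null similarity matches the resampling oracle at n = 38", {
  oracle <- replicate(200, {
    r <- abs(cor(matrix(rnorm(20 * 38), ncol = 20)))
    mean(r[upper.tri(r)])
  })
  set.seed(30)
  vals <- replicate(50, {
    expr <- matrix(rnorm(20 * 38), nrow = 20,
                   dimnames = list(paste0("g", 1:20), paste0("s", 1:38)))
    M <- compute_similarity(expr)$M
    mean(M[upper.tri(M)])
  })
  expect_lt(abs(mean(vals) - mean(oracle)),
            3 * (sd(oracle) / sqrt(200) + sd(vals) / sqrt(50)))
})

test_that("CLR z-scores match hand arithmetic on the 4-gene matrix", {
  z <- clr_transform(hand_sim())$Z
  expect_equal(z["g1", "g2"], 2 / sqrt(3), tolerance = 1e-12)
  # pair below both row means clips to zero: M[g1,g3] = 0.3 is below row 1
  # mean 0.4 and below row 3 mean 0.4
  expect_equal(z["g1", "g3"], 0)
  expect_identical(z, t(z))   # symmetry in (i, j)
})

test_that("flat similarity rows are flagged and contribute z = 0", {
  s <- hand_sim()
  s$M["g4", c("g1", "g2", "g3")] <- 0.3
  s$M[c("g1", "g2", "g3"), "g4"] <- 0.3
  out <- clr_transform(s)
  expect_true("g4" %in% out$flat_rows)
  expect_false(anyNA(out$Z[upper.tri(out$Z)]))
})

test_that("clr_transform is invariant to gene ordering", {
  set.seed(6)
  expr <- matrix(rnorm(12 * 15), 12,
                 dimnames = list(paste0("g", 1:12), paste0("s", 1:15)))
  z1 <- clr_transform(compute_similarity(expr))$Z
  perm <- sample(nrow(expr))
  z2 <- clr_transform(compute_similarity(expr[perm, ]))$Z
  expect_equal(z1, z2[rownames(z1), colnames(z1)], tolerance = 1e-12)
})

test_that("analytic edge p inverts as exp(-z^2/2), pinned at the printed scale", {
  s <- hand_sim()
  sc <- clr_transform(s)
  p <- edge_pvalues(sc, "analytic")
  expect_equal(p["g1", "g3"], 1)              # z = 0, no evidence
  expect_equal(p["g1", "g2"], exp(-(2 / sqrt(3))^2 / 2), tolerance = 1e-12)
  # the early-network cutoff scale: z = sqrt(2 ln(1/0.0051)) gives 0.0051
  z <- sqrt(2 * log(1 / 0.0051))
  expect_equal(exp(-z^2 / 2), 0.0051, tolerance = 1e-12)
})

test_that("permutation mode flags a planted strong edge at p <= 0.001", {
  set.seed(12)
  x <- rnorm(38)
  expr <- rbind(TF1 = x, G1 = x + rnorm(38, sd = 0.05),
                matrix(rnorm(25 * 38), 25,
                       dimnames = list(paste0("n", 1:25), NULL)))
  colnames(expr) <- paste0("s", 1:38)
  sc <- clr_transform(compute_similarity(expr))
  p <- edge_pvalues(sc, "permutation", expr = expr, n_perm = 1000,
                    seed = 4)
  expect_lte(p["TF1", "G1"], 0.001)
})

test_that("permutation-mode p-values are calibrated on null data and the
           analytic mode orders edges consistently", {
  set.seed(31)
  expr <- matrix(rnorm(30 * 20), 30,
                 dimnames = list(paste0("g", 1:30), paste0("s", 1:20)))
  sc <- clr_transform(compute_similarity(expr))
  pp <- edge_pvalues(sc, "permutation", expr = expr, n_perm = 3000,
                     seed = 8)
  pa <- edge_pvalues(sc, "analytic")
  up <- upper.tri(pp)
  n <- sum(up)
  for (alpha in c(0.01, 0.05)) {
    rate <- mean(pp[up] < alpha)
    expect_lt(abs(rate - alpha), 3 * sqrt(alpha * (1 - alpha) / n))
  }
  # analytic p is a monotone transform of the same ordering
  expect_gte(cor(pa[up], pp[up], method = "spearman"), 0.99)
})

test_that("thresholding keeps exactly the retained fraction with a
           deterministic boundary", {
  set.seed(2)
  genes <- c("TF1", paste0("g", 1:10))
  Z <- matrix(0, 11, 11, dimnames = list(genes, genes))
  vals <- seq(0.5, 5, length.out = 10)
  Z["TF1", -1] <- vals; Z[-1, "TF1"] <- vals
  diag(Z) <- NA
  sc <- structure(list(Z = Z, genes = genes, flat_rows = character()),
                  class = "clr_scores")
  ep <- exp(-Z^2 / 2)
  net <- build_tf_network(sc, ep, "TF1", retain_fraction = 0.5)
  expect_equal(nrow(net$edges), 5)           # 10 candidates -> exactly 5
  expect_equal(net$p_threshold, unname(sort(ep["TF1", -1])[5]))
  expect_true(all(net$edges$edge_p <= net$p_threshold))
  discarded <- setdiff(paste0("g", 1:10), net$edges$partner)
  expect_true(all(ep["TF1", discarded] >= net$p_threshold))
  expect_error(build_tf_network(sc, ep, "TFX"), "no TFs")
})

test_that("planted modules separate perfectly at zero noise", {
  tr <- make_panel_truth(n_tf = 2, per_tf = 4, extra = 10, noise_sd = 0,
                         n_samples = 20)
  sim <- simulate_macrophage_expression(tr, 5)
  sc <- clr_transform(compute_similarity(sim$expr))
  cand <- expand.grid(tf = tr$tf_ids, g = rownames(sim$expr),
                      stringsAsFactors = FALSE)
  cand <- cand[cand$tf != cand$g, ]
  z <- sc$Z[cbind(match(cand$tf, rownames(sc$Z)),
                  match(cand$g, colnames(sc$Z)))]
  lab <- paste(cand$tf, cand$g) %in% paste(tr$edge_list$tf,
                                           tr$edge_list$target)
  expect_equal(auroc(z, lab), 1)
})

test_that("hub ranking reproduces the early-network degree table shape", {
  # star fixture with the printed top-hub degrees: 17 and 13 edges
  a_part <- sprintf("a%02d", 1:17)
  b_part <- sprintf("b%02d", 1:13)
  genes <- c("PPARA", "PPARG", a_part, b_part)
  edges <- data.frame(tf = rep(c("PPARA", "PPARG"), c(17, 13)),
                      partner = c(a_part, b_part),
                      z = 3, edge_p = 0.001)
  nodes <- data.frame(gene = genes, is_tf = genes %in% c("PPARA", "PPARG"),
                      degree = c(17L, 13L, rep(1L, 30)))
  net <- structure(list(edges = edges, nodes = nodes, p_threshold = 0.001,
                        member_count = 32, retained_fraction = 0.5,
                        n_candidates = 60),
                   class = "tf_network")
  hubs <- rank_master_regulators(net, top_k = 5)
  expect_identical(hubs$tf, c("PPARA", "PPARG"))
  expect_identical(hubs$connections, c(17L, 13L))
  # equal degrees break ties lexicographically and stably
  nodes$degree[1:2] <- 10L
  net$nodes <- nodes
  expect_identical(rank_master_regulators(net)$tf, c("PPARA", "PPARG"))
  # top_k beyond the TF count returns all TFs
  expect_equal(nrow(rank_master_regulators(net, top_k = 50)), 2)
})

test_that("an edgeless network warns and degree bookkeeping conserves", {
  tr <- make_panel_truth(n_tf = 3, per_tf = 3, extra = 10, n_samples = 12)
  sim <- simulate_macrophage_expression(tr, 9)
  sc <- clr_transform(compute_similarity(sim$expr))
  ep <- edge_pvalues(sc, "analytic")
  net <- build_tf_network(sc, ep, tr$tf_ids, retain_fraction = 0.5)
  # every edge contributes two endpoint degrees
  expect_equal(sum(net$nodes$degree), 2 * nrow(net$edges))
  expect_true(all(net$edges$tf %in% tr$tf_ids))
  expect_equal(net$member_count, sum(net$nodes$degree >= 1))
  empty <- net
  empty$edges <- net$edges[0, ]
  expect_warning(h <- rank_master_regulators(empty), "edgeless")
  expect_equal(nrow(h), 0)
})
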