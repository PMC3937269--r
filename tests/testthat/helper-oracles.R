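# Independent oracles used to freeze expected values.  These deliberately do
# not share code with the package implementation.

# Brute-force Benjamini-Hochberg: sort, compare p_(i) <= i*q/m, reject up to
# the largest i that passes.
bh_brute <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(ok)) rej[o[seq_len(max(ok))]] <- TRUE
  rej
}

# Exhaustive hypergeometric upper tail: enumerate every size-X draw from a
# population of M genes whose first K are the network members.
hyper_enum <- function(M, K, X, x) {
  if (X == 0) return(as.numeric(x <= 0))
  draws <- utils::combn(M, X)
  mean(colSums(draws <= K) >= x)
}

# Rank-based AUROC (Wilcoxon identity).
auroc <- function(scores, labels) {
  r <- rank(scores)
  pos <- sum(labels)
  neg <- sum(!labels)
  (sum(r[labels]) - pos * (pos + 1) / 2) / (pos * neg)
}

# A small macrophage panel truth with planted TF modules.
make_panel_truth <- function(n_tf = 20, per_tf = 8, extra = 90,
                             beta = 1, noise_sd = 0.5, n_samples = 38) {
  tfs <- sprintf("TF%02d", seq_len(n_tf))
  targets <- sprintf("TG%03d", seq_len(n_tf * per_tf))
  macrophage_panel_truth(
    tfs,
    data.frame(tf = rep(tfs, each = per_tf), target = targets, beta = beta),
    noise_sd = noise_sd, n_samples = n_samples,
    background_genes = sprintf("BG%03d", seq_len(extra)))
}

# A small genotype truth: `n_snps` per chromosome, optional LD block on the
# first SNPs of chromosome "1", optional cis gene at the block seed.
make_genotype_truth <- function(n_snps = 100, chrs = c("1", "2"),
                                block = NULL, block_r2 = 0.95,
                                cis_effect = NULL, enriched = character(),
                                p_hit = 0.05, maf = 0.3) {
  st <- do.call(rbind, lapply(chrs, function(ch)
    data.frame(snp = sprintf("rs%s_%03d", ch, seq_len(n_snps)), chr = ch,
               pos = seq(1e5, by = 5e4, length.out = n_snps), maf = maf)))
  blocks <- if (!is.null(block))
    list(list(snps = st$snp[seq_len(block)], r2 = block_r2)) else list()
  tss <- data.frame(gene = "G1", chr = "1", tss = 2e5)
  cis <- if (!is.null(cis_effect))
    data.frame(gene = "G1", snp = st$snp[1], effect = cis_effect)
  else data.frame(gene = character(), snp = character(), effect = numeric())
  genotype_truth(st, blocks, cis, tss, gwas_enriched_snps = enriched,
                 p_hit = p_hit)
}
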