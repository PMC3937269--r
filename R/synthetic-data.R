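# Generators for every input the pipeline consumes, each carrying its planted
# ground truth so downstream detectors can be scored against known answers.
# All noise is Gaussian on the log2 scale (the post-normalisation scale the
# analyses operate on) and every generator is bit-reproducible given
# (parameters, seed).

#' Ground truth for a macrophage co-expression panel
#'
#' Describes a gene universe containing transcription factors (TFs), planted
#' TF-to-target regulatory edges, and free background genes, mirroring the
#' kind of 38-profile macrophage panel used for TF-network inference.
#'
#' @param tf_ids character vector of TF gene identifiers.
#' @param edge_list data.frame with columns `tf`, `target`, `beta` (linear
#'   effect of the TF's expression on the target, log2 scale).
#' @param noise_sd residual standard deviation of target genes.
#' @param n_samples number of expression profiles (default 38).
#' @param background_genes additional unconnected genes completing the
#'   universe; defaults to none.
#' @return An object of class `macrophage_panel_truth`.
#' @export
#' @examples
#' tr <- macrophage_panel_truth("TF1", data.frame(tf = "TF1", target = "G1",
#'                                                beta = 1))
macrophage_panel_truth <- function(tf_ids, edge_list, noise_sd = 0.5,
                                   n_samples = 38L,
                                   background_genes = character()) {
  stopifnot(is.character(tf_ids), length(tf_ids) >= 1)
  stop_if_not_named_df(edge_list, c("tf", "target", "beta"), "edge_list")
  if (nrow(edge_list) && !all(edge_list$tf %in% tf_ids))
    stop("every planted edge must have a TF endpoint listed in tf_ids")
  if (nrow(edge_list) && !all(is.finite(edge_list$beta)))
    stop("planted effect sizes must be finite")
  if (n_samples < 4) stop("n_samples must be >= 4")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  genes <- unique(c(tf_ids, edge_list$target, background_genes))
  structure(list(tf_ids = tf_ids,
                 edge_list = edge_list,
                 noise_sd = noise_sd,
                 n_samples = as.integer(n_samples),
                 genes = genes),
            class = "macrophage_panel_truth")
}

#' Simulate a macrophage co-expression panel with planted TF modules
#'
#' Each TF (and each background gene) is an independent standard Gaussian
#' across samples; each planted target is `beta * TF + Gaussian(noise_sd)`
#' (summed over its TF parents when a target has several).
#'
#' @param truth a [macrophage_panel_truth()] object.
#' @param seed integer seed (required; generators are reproducible by
#'   construction).
#' @return A list with `expr` (genes x samples matrix) and `truth`.
#' @export
simulate_macrophage_expression <- function(truth, seed) {
  stopifnot(inherits(truth, "macrophage_panel_truth"))
  if (missing(seed)) stop("seed must be supplied")
  genes <- truth$genes
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers in the gene universe: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  n <- truth$n_samples
  set.seed(seed)
  targets <- unique(truth$edge_list$target)
  drivers <- setdiff(genes, targets)
  expr <- matrix(NA_real_, nrow = length(genes), ncol = n,
                 dimnames = list(genes, sprintf("S%02d", seq_len(n))))
  expr[drivers, ] <- matrix(stats::rnorm(length(drivers) * n), ncol = n)
  for (g in targets) {
    parents <- truth$edge_list[truth$edge_list$target == g, , drop = FALSE]
    base <- colSums(expr[parents$tf, , drop = FALSE] * parents$beta)
    expr[g, ] <- base + stats::rnorm(n, sd = truth$noise_sd)
  }
  list(expr = expr, truth = truth)
}

#' Design of a two-arm multi-timepoint mouse expression study
#'
#' Encodes the regression-study layout: per timepoint (lesion stage) there are
#' high-cholesterol littermate controls, mice sacrificed immediately after
#' plasma cholesterol lowering (PCL), and mice sacrificed 10 weeks after PCL.
#' PCL-responsive truth is a control-vs-immediately-after shift;
#' regression-reactive truth is an immediately-after-vs-10-weeks shift.
#'
#' @param timepoints ordered stage labels (default weeks 30, 40, 50).
#' @param n_per_cell replicates per timepoint x cell; a named vector with
#'   entries `control`, `post_pcl`, `regression_10wk`, or a single number used
#'   for all three.  All entries must be >= 3.
#' @param n_genes size of the gene universe.
#' @param planted_pcl_genes,planted_reactive_genes named lists (one element
#'   per timepoint label) of data.frames with columns `gene`, `lfc` (log2
#'   effect).
#' @param noise_sd residual standard deviation (log2 scale).
#' @param baseline_mean mean baseline log2 expression.
#' @return An object of class `timecourse_design`.
#' @export
timecourse_design <- function(timepoints = c(30, 40, 50),
                              n_per_cell = c(control = 6, post_pcl = 6,
                                             regression_10wk = 10),
                              n_genes = 21000L,
                              planted_pcl_genes = NULL,
                              planted_reactive_genes = NULL,
                              noise_sd = 0.5,
                              baseline_mean = 7) {
  cells <- c("control", "post_pcl", "regression_10wk")
  if (length(n_per_cell) == 1L) n_per_cell <- stats::setNames(rep(n_per_cell, 3), cells)
  stopifnot(all(cells %in% names(n_per_cell)))
  if (any(n_per_cell[cells] < 3)) stop("replicate counts must be >= 3")
  tp <- as.character(timepoints)
  empty <- stats::setNames(rep(list(data.frame(gene = character(),
                                               lfc = numeric())), length(tp)), tp)
  planted_pcl_genes <- planted_pcl_genes %||% empty
  planted_reactive_genes <- planted_reactive_genes %||% empty
  for (lst in list(planted_pcl_genes, planted_reactive_genes)) {
    stopifnot(all(tp %in% names(lst)))
    lapply(lst, stop_if_not_named_df, cols = c("gene", "lfc"),
           what = "each planted gene table")
  }
  structure(list(timepoints = tp,
                 n_per_cell = n_per_cell[cells],
                 n_genes = as.integer(n_genes),
                 planted_pcl_genes = planted_pcl_genes[tp],
                 planted_reactive_genes = planted_reactive_genes[tp],
                 noise_sd = noise_sd,
                 baseline_mean = baseline_mean),
            class = "timecourse_design")
}

#' Simulate the two-arm timecourse expression study
#'
#' Planted PCL-responsive genes are shifted by their log2 effect in both the
#' immediately-after-PCL and 10-weeks-after cells of their timepoint (the PCL
#' response persists), so they separate control vs immediately-after but not
#' the regression contrast.  Planted regression-reactive genes are shifted
#' only in the 10-weeks-after cell.  All other genes are exchangeable across
#' cells.
#'
#' @param design a [timecourse_design()].
#' @param seed integer seed.
#' @return A list with `expr` (genes x samples), `annotations` (data.frame
#'   with `sample_id`, `timepoint`, `cell`), and `truth` (the design).
#' @export
simulate_timecourse_expression <- function(design, seed) {
  stopifnot(inherits(design, "timecourse_design"))
  if (missing(seed)) stop("seed must be supplied")
  if (any(design$n_per_cell < 2)) stop("n_per_cell must be >= 2")
  set.seed(seed)
  genes <- sprintf("MG%05d", seq_len(design$n_genes))
  ann <- do.call(rbind, lapply(design$timepoints, function(tpt) {
    do.call(rbind, lapply(names(design$n_per_cell), function(cell) {
      n <- design$n_per_cell[[cell]]
      data.frame(timepoint = tpt, cell = cell, rep = seq_len(n))
    }))
  }))
  ann$sample_id <- sprintf("w%s_%s_%d", ann$timepoint, ann$cell, ann$rep)
  baseline <- stats::rnorm(length(genes), mean = design$baseline_mean, sd = 1)
  expr <- matrix(stats::rnorm(length(genes) * nrow(ann), sd = design$noise_sd),
                 nrow = length(genes),
                 dimnames = list(genes, ann$sample_id)) + baseline
  for (tpt in design$timepoints) {
    pcl <- design$planted_pcl_genes[[tpt]]
    rea <- design$planted_reactive_genes[[tpt]]
    post <- ann$sample_id[ann$timepoint == tpt & ann$cell != "control"]
    reg <- ann$sample_id[ann$timepoint == tpt & ann$cell == "regression_10wk"]
    if (nrow(pcl)) {
      bad <- setdiff(pcl$gene, genes)
      if (length(bad)) stop("planted genes outside universe: ",
                            paste(utils::head(bad, 5), collapse = ", "))
      expr[pcl$gene, post] <- expr[pcl$gene, post] + pcl$lfc
    }
    if (nrow(rea)) {
      bad <- setdiff(rea$gene, genes)
      if (length(bad)) stop("planted genes outside universe: ",
                            paste(utils::head(bad, 5), collapse = ", "))
      expr[rea$gene, reg] <- expr[rea$gene, reg] + rea$lfc
    }
  }
  list(expr = expr,
       annotations = ann[, c("sample_id", "timepoint", "cell")],
       truth = design)
}

#' Ground truth for genotypes, cis-eQTL effects and a GWAS
#'
#' @param snp_table data.frame with `snp`, `chr`, `pos`, `maf`; positions must
#'   be strictly increasing within chromosome and MAF in (0, 0.5].
#' @param ld_blocks list of lists, each with `snps` (members, first one acts
#'   as the block seed) and `r2` (target pairwise r-squared in (0, 1]).
#' @param cis_effects data.frame `gene`, `snp`, `effect`: planted additive
#'   dosage effects on expression; each SNP must lie within `cis_window` of
#'   its gene's TSS.
#' @param gene_tss data.frame `gene`, `chr`, `tss`.
#' @param gwas_enriched_snps SNP ids whose association P is drawn below 0.05
#'   with probability `p_hit` (others are Uniform(0,1), i.e. a 5% hit rate).
#' @param p_hit probability of a nominal GWAS hit for enriched SNPs.
#' @param cis_window window around the TSS used to validate planted effects.
#' @return An object of class `genotype_truth`.
#' @export
genotype_truth <- function(snp_table, ld_blocks = list(),
                           cis_effects = data.frame(gene = character(),
                                                    snp = character(),
                                                    effect = numeric()),
                           gene_tss = data.frame(gene = character(),
                                                 chr = character(),
                                                 tss = numeric()),
                           gwas_enriched_snps = character(),
                           p_hit = 0.05,
                           cis_window = 1e6) {
  stop_if_not_named_df(snp_table, c("snp", "chr", "pos", "maf"), "snp_table")
  if (any(snp_table$maf <= 0 | snp_table$maf > 0.5))
    stop("MAF must lie in (0, 0.5]")
  for (ch in unique(snp_table$chr)) {
    p <- snp_table$pos[snp_table$chr == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  for (b in ld_blocks) {
    if (is.null(b$r2) || b$r2 <= 0 || b$r2 > 1)
      stop("target r2 must lie in (0, 1]")
    if (!all(b$snps %in% snp_table$snp))
      stop("LD block members must be listed in snp_table")
  }
  stop_if_not_named_df(cis_effects, c("gene", "snp", "effect"), "cis_effects")
  stop_if_not_named_df(gene_tss, c("gene", "chr", "tss"), "gene_tss")
  if (nrow(cis_effects)) {
    m <- merge(merge(cis_effects, gene_tss, by = "gene"),
               snp_table, by = "snp")
    off <- m$chr.x != m$chr.y | abs(m$pos - m$tss) > cis_window
    if (any(off))
      stop("planted cis SNPs must lie within the cis window of their gene's TSS: ",
           paste(m$snp[off], collapse = ", "))
  }
  structure(list(snp_table = snp_table, ld_blocks = ld_blocks,
                 cis_effects = cis_effects, gene_tss = gene_tss,
                 gwas_enriched_snps = gwas_enriched_snps,
                 p_hit = p_hit, cis_window = cis_window),
            class = "genotype_truth")
}

#' Simulate genotype dosages, an eQTL expression matrix, and GWAS summary P
#'
#' Dosages are sums of two haplotypes drawn per MAF.  Within an LD block every
#' member shares the block seed's MAF and copies the seed haplotype allele
#' with probability `sqrt(r2)` (else redraws), so pairwise dosage r-squared
#' equals the target in expectation; a copy probability of 1 gives perfect LD.
#' Genes with planted cis effects get `expression = effect * dosage + noise`;
#' all other genes in `gene_tss` are independent Gaussians.  GWAS P-values
#' are Uniform(0,1) except for enriched SNPs, which fall below 0.05 with
#' probability `p_hit`.
#'
#' @param truth a [genotype_truth()].
#' @param n_individuals number of individuals (>= 50 for stable LD).
#' @param seed integer seed.
#' @param noise_sd residual sd of cis-affected gene expression.
#' @return A list with `dosage` (SNPs x individuals), `gwas` (data.frame
#'   `snp`, `chr`, `pos`, `p`, `maf`), `expr` (genes x individuals), `truth`.
#' @export
simulate_genotypes_gwas <- function(truth, n_individuals = 156L, seed,
                                    noise_sd = 0.5) {
  stopifnot(inherits(truth, "genotype_truth"))
  if (missing(seed)) stop("seed must be supplied")
  if (n_individuals < 50) stop("n_individuals must be >= 50 for stable LD")
  set.seed(seed)
  st <- truth$snp_table
  n <- as.integer(n_individuals)
  ids <- sprintf("I%03d", seq_len(n))
  # two haplotypes per individual per SNP
  hap <- array(0L, dim = c(nrow(st), n, 2),
               dimnames = list(st$snp, ids, NULL))
  in_block <- unlist(lapply(truth$ld_blocks, function(b) b$snps[-1]))
  free <- setdiff(st$snp, in_block)
  if (length(free)) {
    probs <- st$maf[match(free, st$snp)]
    # snp index varies fastest, matching rbinom's prob recycling
    hap[free, , ] <- array(stats::rbinom(length(free) * 2L * n, 1L, probs),
                           dim = c(length(free), n, 2))
  }
  for (b in truth$ld_blocks) {
    seed_snp <- b$snps[1]
    copy_p <- sqrt(b$r2)
    maf <- st$maf[st$snp == seed_snp]
    for (s in b$snps[-1]) {
      keep <- stats::rbinom(2L * n, 1L, copy_p) == 1L
      fresh <- stats::rbinom(2L * n, 1L, maf)
      hap[s, , ] <- ifelse(keep, hap[seed_snp, , ], fresh)
    }
  }
  dosage <- hap[, , 1] + hap[, , 2]
  storage.mode(dosage) <- "integer"
  # expression for eQTL detection
  genes <- truth$gene_tss$gene
  expr <- matrix(stats::rnorm(length(genes) * n),
                 nrow = length(genes), dimnames = list(genes, ids))
  if (nrow(truth$cis_effects)) {
    for (k in seq_len(nrow(truth$cis_effects))) {
      g <- truth$cis_effects$gene[k]; s <- truth$cis_effects$snp[k]
      expr[g, ] <- truth$cis_effects$effect[k] * dosage[s, ] +
        stats::rnorm(n, sd = noise_sd)
    }
  }
  # GWAS summary P-values
  p <- stats::runif(nrow(st))
  enr <- st$snp %in% truth$gwas_enriched_snps
  if (any(enr)) {
    hit <- stats::rbinom(sum(enr), 1L, truth$p_hit) == 1L
    u <- stats::runif(sum(enr))
    p[enr] <- ifelse(hit, 0.05 * u, 0.05 + 0.95 * u)
  }
  gwas <- data.frame(snp = st$snp, chr = st$chr, pos = st$pos,
                     p = p, maf = st$maf)
  list(dosage = dosage, gwas = gwas, expr = expr, truth = truth)
}

#' Ground truth for an siRNA knockdown screen on a fixed gene panel
#'
#' @param target_tf the silenced TF (must be on the panel).
#' @param panel_genes the fixed gene panel; defaults to a synthetic 673-gene
#'   panel containing the target.
#' @param knockdown_fraction relative mRNA reduction of the target, in (0,1).
#' @param affected_genes data.frame `gene`, `lfc`: planted downstream shifts
#'   (log2) in the knockdown arm.
#' @param ce_shift planted relative change in cholesterol-ester accumulation
#'   (e.g. 0.12 for +12%).
#' @return An object of class `perturbation_truth`.
#' @export
perturbation_truth <- function(target_tf, panel_genes = NULL,
                               knockdown_fraction = 0.8,
                               affected_genes = data.frame(gene = character(),
                                                           lfc = numeric()),
                               ce_shift = 0) {
  if (is.null(panel_genes))
    panel_genes <- unique(c(target_tf, sprintf("PNL%04d", seq_len(673L))))[1:673]
  stopifnot(is.character(panel_genes))
  if (!target_tf %in% panel_genes) stop("target_tf must be on the panel")
  if (knockdown_fraction <= 0 || knockdown_fraction >= 1)
    stop("knockdown_fraction must lie in (0, 1)")
  stop_if_not_named_df(affected_genes, c("gene", "lfc"), "affected_genes")
  if (!all(affected_genes$gene %in% panel_genes))
    stop("affected genes must be on the panel")
  structure(list(target_tf = target_tf, panel_genes = panel_genes,
                 knockdown_fraction = knockdown_fraction,
                 affected_genes = affected_genes, ce_shift = ce_shift),
            class = "perturbation_truth")
}

#' Simulate an siRNA knockdown screen and CE readout
#'
#' Control samples are Gaussian log2 expression around a per-gene baseline.
#' In the knockdown arm the target's expression is reduced by
#' `knockdown_fraction` (a `log2(1 - kf)` shift), affected genes are shifted
#' by their planted log2 effects, and cholesterol-ester (CE) values are drawn
#' `Normal(100 * (1 + ce_shift), ce_sd)` versus `Normal(100, ce_sd)` in the
#' control arm.
#'
#' @param truth a [perturbation_truth()].
#' @param n_replicates replicates per arm (>= 3).
#' @param seed integer seed.
#' @param noise_sd residual sd (log2) of the panel expression.
#' @param baseline_mean mean baseline log2 expression.
#' @param ce_sd sd of the relative CE values.
#' @return A list with `control`, `knockdown` (panel x replicates matrices),
#'   `ce` (data.frame `arm`, `ce`), `truth`.
#' @export
simulate_perturbation_screen <- function(truth, n_replicates = 6L, seed,
                                         noise_sd = 0.25, baseline_mean = 8,
                                         ce_sd = 10) {
  stopifnot(inherits(truth, "perturbation_truth"))
  if (missing(seed)) stop("seed must be supplied")
  if (n_replicates < 3) stop("n_replicates must be >= 3 (no variance estimate)")
  set.seed(seed)
  genes <- truth$panel_genes
  n <- as.integer(n_replicates)
  baseline <- stats::rnorm(length(genes), baseline_mean, 1)
  mk <- function(prefix) {
    matrix(stats::rnorm(length(genes) * n, sd = noise_sd), nrow = length(genes),
           dimnames = list(genes, sprintf("%s%d", prefix, seq_len(n)))) + baseline
  }
  control <- mk("CTL")
  kd <- mk("KD")
  kd[truth$target_tf, ] <- kd[truth$target_tf, ] +
    log2(1 - truth$knockdown_fraction)
  if (nrow(truth$affected_genes))
    kd[truth$affected_genes$gene, ] <- kd[truth$affected_genes$gene, ] +
      truth$affected_genes$lfc
  ce <- data.frame(
    arm = rep(c("control", "knockdown"), each = n),
    ce = c(stats::rnorm(n, 100, ce_sd),
           stats::rnorm(n, 100 * (1 + truth$ce_shift), ce_sd)))
  list(control = control, knockdown = kd, ce = ce, truth = truth)
}

#' Simulate per-mouse histology area percentages with missingness
#'
#' Draws per-mouse stained-area percentages (SM22a, collagen, CD68,
#' Oil-Red-O) and lesion burden from group-level Normal distributions, clamps
#' them to the legal percentage range, and deletes measurement cells
#' completely at random at `missing_rate`.
#'
#' @param group_means data.frame with a `group` column and numeric columns
#'   `sm22`, `collagen`, `cd68`, `oro`, `burden` (all percentages in
#'   `[0, 100]`).
#' @param group_sds same shape as `group_means` (or a single number recycled).
#' @param n_mice mice per group (single number or vector per group).
#' @param missing_rate probability a measurement cell is deleted; must be < 1.
#' @param seed integer seed.
#' @return A data.frame `mouse_id`, `group`, `sm22`, `collagen`, `cd68`,
#'   `oro`, `burden` with `NA` for missing cells.
#' @export
simulate_histology <- function(group_means, group_sds = 1, n_mice = 8L,
                               missing_rate = 0, seed) {
  fields <- c("sm22", "collagen", "cd68", "oro", "burden")
  stop_if_not_named_df(group_means, c("group", fields), "group_means")
  if (missing(seed)) stop("seed must be supplied")
  if (missing_rate >= 1) stop("missing_rate must be < 1")
  if (missing_rate < 0) stop("missing_rate must be >= 0")
  vals <- as.matrix(group_means[, fields])
  if (any(vals < 0 | vals > 100)) stop("area percentages must lie in [0, 100]")
  ng <- nrow(group_means)
  if (is.numeric(group_sds) && !is.data.frame(group_sds)) {
    sds <- matrix(group_sds, nrow = ng, ncol = length(fields),
                  dimnames = list(NULL, fields))
  } else {
    stop_if_not_named_df(group_sds, fields, "group_sds")
    sds <- as.matrix(group_sds[, fields])
  }
  n_mice <- rep_len(n_mice, ng)
  set.seed(seed)
  rows <- lapply(seq_len(ng), function(g) {
    m <- matrix(NA_real_, nrow = n_mice[g], ncol = length(fields),
                dimnames = list(NULL, fields))
    for (j in seq_along(fields))
      m[, j] <- pmin(100, pmax(0, stats::rnorm(n_mice[g], vals[g, j], sds[g, j])))
    data.frame(group = group_means$group[g], m)
  })
  out <- do.call(rbind, rows)
  out <- data.frame(mouse_id = sprintf("M%03d", seq_len(nrow(out))), out)
  if (missing_rate > 0) {
    cells <- as.matrix(out[, fields])
    drop <- matrix(stats::runif(length(cells)) < missing_rate,
                   nrow = nrow(cells))
    cells[drop] <- NA_real_
    out[, fields] <- cells
  }
  rownames(out) <- NULL
  out
}

#' Save or load a ground-truth object as JSON
#'
#' Truth objects round-trip losslessly (full double precision) through these
#' writers, so simulated studies can be archived next to their outputs.
#'
#' @param truth a truth object from this module.
#' @param path file path.
#' @return `write_truth` returns `path` invisibly; `read_truth` returns the
#'   restored object.
#' @export
write_truth <- function(truth, path) {
  cls <- class(truth)[1]
  payload <- unclass(truth)
  # named atomic vectors lose their names as JSON arrays; keep them as objects
  payload <- lapply(payload, function(x)
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x)
  jsonlite::write_json(list(class = cls, data = payload), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  data <- obj$data
  # data.frames survive simplifyVector, but empty ones come back as bare
  # lists with no columns; restore the expected column skeleton
  as_df <- function(x, template) {
    d <- as.data.frame(x)
    if (!ncol(d)) template else d
  }
  gene_lfc <- data.frame(gene = character(), lfc = numeric())
  rebuild <- switch(obj$class,
    macrophage_panel_truth = function(d) {
      el <- as_df(d$edge_list, data.frame(tf = character(),
                                          target = character(),
                                          beta = numeric()))
      macrophage_panel_truth(d$tf_ids, el, d$noise_sd, d$n_samples,
                             setdiff(d$genes, c(d$tf_ids, el$target)))
    },
    timecourse_design = function(d)
      timecourse_design(d$timepoints, unlist(d$n_per_cell), d$n_genes,
                        lapply(d$planted_pcl_genes, as_df, gene_lfc),
                        lapply(d$planted_reactive_genes, as_df, gene_lfc),
                        d$noise_sd, d$baseline_mean),
    genotype_truth = function(d) {
      blocks <- d$ld_blocks
      blocks <- if (is.data.frame(blocks)) {
        lapply(seq_len(nrow(blocks)), function(i)
          list(snps = unlist(blocks$snps[[i]]), r2 = blocks$r2[[i]]))
      } else {
        lapply(blocks, function(b) list(snps = unlist(b$snps), r2 = b$r2))
      }
      genotype_truth(as.data.frame(d$snp_table), blocks,
                     as_df(d$cis_effects,
                           data.frame(gene = character(), snp = character(),
                                      effect = numeric())),
                     as.data.frame(d$gene_tss),
                     unlist(d$gwas_enriched_snps) %||% character(),
                     d$p_hit, d$cis_window)
    },
    perturbation_truth = function(d)
      perturbation_truth(d$target_tf, d$panel_genes, d$knockdown_fraction,
                         as_df(d$affected_genes, gene_lfc), d$ce_shift),
    stop("unknown truth class: ", obj$class))
  rebuild(data)
}
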