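# End-to-end pipeline over simulated inputs with known ground truth.
# Every stage seeds its own RNG stream via derive_seed(), so a fixed
# configuration reproduces all outputs byte for byte.

#' Generator sizes and planted effects for a pipeline run
#'
#' Defaults mirror the study conditions: three lesion stages (weeks 30, 40,
#' 50) with 6 controls, 6 immediately-after-PCL and 10 ten-weeks-after
#' profiles per stage over a 21,000-gene universe (the gene-level content of
#' the array platform); planted PCL-responsive set sizes 238, 1306 and 2231
#' and regression-reactive sizes 42, 1556 and 6273 genes; an ortholog table
#' dropping 9.7% of mouse genes (the early-set mapping loss, 238 to 215); a
#' 38-profile macrophage panel with planted TF modules; 156 genotyped
#' individuals; a 673-gene screen panel with 15 planted network hits and a
#' +12% planted CE shift.
#'
#' @param n_genes mouse gene universe size.
#' @param pcl_sizes,reactive_sizes named planted-set sizes per stage.
#' @param lfc planted absolute log2 effect for timecourse genes.
#' @param noise_sd timecourse residual sd (log2).
#' @param n_per_cell replicates per timepoint cell.
#' @param ortholog_drop fraction of mouse genes without a human ortholog.
#' @param n_tf,targets_per_tf,panel_extra,beta,clr_noise_sd,n_profiles
#'   macrophage co-expression panel: TF count, targets per TF, unconnected
#'   background genes, planted edge effect, residual sd, sample count.
#' @param n_snps,n_chr,block_size,block_r2,n_cis,cis_effect,p_hit,n_individuals
#'   genotype/GWAS fixture: SNP count, chromosomes, LD block size, target
#'   block r-squared, planted cis-eQTL count, cis effect size, nominal-hit
#'   probability of enriched SNPs, genotyped individuals.
#' @param screen_panel_size,screen_reps,screen_hits,screen_extra,screen_lfc,kd_fraction,ce_shift,ce_sd
#'   knockdown screen: panel size, replicates per arm, planted affected
#'   genes inside the network, additional affected genes outside it, their
#'   log2 shift, target knockdown fraction, planted CE shift and CE sd.
#' @param hist_n_mice,hist_missing_rate histology mice per group and
#'   missing-cell rate.
#' @return A list of class `pipeline_sizes`.
#' @export
pipeline_sizes <- function(n_genes = 21000L,
                           pcl_sizes = c("30" = 238L, "40" = 1306L,
                                         "50" = 2231L),
                           reactive_sizes = c("30" = 42L, "40" = 1556L,
                                              "50" = 6273L),
                           lfc = 2, noise_sd = 0.25,
                           n_per_cell = c(control = 6, post_pcl = 6,
                                          regression_10wk = 10),
                           ortholog_drop = 0.097,
                           n_tf = 20L, targets_per_tf = 8L,
                           panel_extra = 90L, beta = 1, clr_noise_sd = 0.5,
                           n_profiles = 38L,
                           n_snps = 1500L, n_chr = 4L, block_size = 5L,
                           block_r2 = 0.95, n_cis = 40L, cis_effect = 1,
                           p_hit = 0.10, n_individuals = 156L,
                           screen_panel_size = 673L, screen_reps = 6L,
                           screen_hits = 15L, screen_extra = 10L,
                           screen_lfc = 1, kd_fraction = 0.8,
                           ce_shift = 0.12, ce_sd = 10,
                           hist_n_mice = 8L, hist_missing_rate = 0.16) {
  structure(as.list(environment()), class = "pipeline_sizes")
}

# Printed-table group means for the simulated histology (early-lesion arm:
# before PCL, 10 and 20 weeks after; stains and burden as percents).
default_histology_means <- function() {
  data.frame(
    group = c("before", "pcl_10wk", "pcl_20wk"),
    sm22 = c(2.0, 3.0, 3.6),
    collagen = c(3.0, 5.7, 6.6),
    cd68 = c(5.1, 2.0, 0.2),
    oro = c(5.6, 4.0, 2.7),
    burden = c(4.3, 1.5, 0.5))
}

#' Run the full pipeline on simulated data
#'
#' Simulates the timecourse study, defines PCL-responsive and
#' regression-reactive gene sets per stage, maps the early sets to human
#' orthologs, measures CAD/MI risk enrichment of the early causal set
#' against a matched resampling null (with the early reactive set as the
#' negative control), infers the CLR TF network of the macrophage panel and
#' ranks its hubs, validates the top hub with a simulated siRNA screen
#' (affected fraction, hypergeometric specificity, CE change), and computes
#' the histology stability statistics.  All requested stage outputs plus a
#' reproduction manifest are written under `outdir`.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created if needed).
#' @param sizes a [pipeline_sizes()].
#' @param stages which stage outputs to write; all computations needed by a
#'   requested stage are performed regardless.
#' @return A summary list (invisibly returns it after writing
#'   `summary.json`): member counts per stage, enrichment results, hub
#'   table, screen and phenotype statistics, and the manifest path.
#' @export
run_pipeline <- function(config = run_config(), outdir,
                         sizes = pipeline_sizes(),
                         stages = c("simulate", "gene-sets", "enrich",
                                    "network", "perturb", "phenotype")) {
  stopifnot(inherits(config, "run_config"), inherits(sizes, "pipeline_sizes"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(stage, fn, name) {
    if (stage %in% stages) {
      path <- file.path(outdir, name)
      fn(path)
      written <<- c(written, path)
    }
  }
  summary <- list(seed = config$seed)

  ## -- simulate + gene sets -------------------------------------------------
  tps <- c("30", "40", "50")
  set.seed(derive_seed(config$seed, "design"))
  genes <- sprintf("MG%05d", seq_len(sizes$n_genes))
  plant <- function(ns) {
    out <- lapply(tps, function(tp) {
      g <- sample(genes, ns[[tp]])
      data.frame(gene = g,
                 lfc = sizes$lfc * sample(c(-1, 1), length(g), replace = TRUE))
    })
    stats::setNames(out, tps)
  }
  pcl_truth <- plant(sizes$pcl_sizes)
  # reactive truth avoids the same stage's PCL genes so the two contrasts
  # carry disjoint planted signal within a timepoint
  reactive_truth <- stats::setNames(lapply(tps, function(tp) {
    g <- sample(setdiff(genes, pcl_truth[[tp]]$gene),
                sizes$reactive_sizes[[tp]])
    data.frame(gene = g,
               lfc = sizes$lfc * sample(c(-1, 1), length(g), replace = TRUE))
  }), tps)
  design <- timecourse_design(timepoints = tps, n_per_cell = sizes$n_per_cell,
                              n_genes = sizes$n_genes,
                              planted_pcl_genes = pcl_truth,
                              planted_reactive_genes = reactive_truth,
                              noise_sd = sizes$noise_sd)
  tc <- simulate_timecourse_expression(design,
                                       derive_seed(config$seed, "timecourse"))
  emit("simulate", function(p) write_annotations(tc$annotations, p),
       "sample_annotations.tsv")
  emit("simulate", function(p) write_truth(design, p),
       "timecourse_truth.json")

  de_cfg <- de_config(fdr_method = config$fdr_method,
                      fdr_threshold = config$fdr_threshold,
                      exclude_samples = config$excluded_samples)
  stage_sets <- lapply(tps, function(tp)
    define_stage_gene_sets(tc$expr, tc$annotations, tp, de_cfg))
  names(stage_sets) <- tps
  all_sets <- unlist(stage_sets, recursive = FALSE)
  emit("gene-sets", function(p) write_gmt(all_sets, p), "gene_sets.gmt")
  for (nm in names(all_sets)) {
    s <- all_sets[[nm]]
    emit("gene-sets", local({
      s_ <- s
      function(p) write_gene_set_tsv(s_, p)
    }), sprintf("de_%s_%s.tsv", s$stage, s$contrast))
  }
  summary$member_counts <- lapply(stage_sets, function(x)
    list(pcl_responsive = length(x$pcl_responsive$members),
         regression_reactive = length(x$regression_reactive$members)))

  ## -- ortholog map ---------------------------------------------------------
  set.seed(derive_seed(config$seed, "orthologs"))
  keep <- stats::runif(length(genes)) >= sizes$ortholog_drop
  orth <- data.frame(mouse_id = genes[keep],
                     human_id = sub("^MG", "HG", genes[keep]),
                     source = "synthetic_1to1", stringsAsFactors = FALSE)
  causal_h <- map_orthologs(stage_sets[["30"]]$pcl_responsive, orth)
  reactive_h <- map_orthologs(stage_sets[["30"]]$regression_reactive, orth)
  summary$orthologs <- list(causal_mapped = length(causal_h$human_ids),
                            causal_unmapped = causal_h$n_unmapped)

  ## -- risk enrichment (early causal vs early reactive) ---------------------
  hgenes <- unique(c(causal_h$human_ids, reactive_h$human_ids))
  set.seed(derive_seed(config$seed, "genotype-design"))
  per_chr <- ceiling(sizes$n_snps / sizes$n_chr)
  snp_table <- do.call(rbind, lapply(seq_len(sizes$n_chr), function(ch)
    data.frame(snp = sprintf("rs%d_%04d", ch, seq_len(per_chr)),
               chr = as.character(ch),
               pos = sort(sample(1:2e8, per_chr)),
               maf = stats::runif(per_chr, 0.08, 0.5))))
  # gene TSS: spread the ortholog universe over the chromosomes
  tss <- data.frame(gene = hgenes,
                    chr = as.character(rep_len(seq_len(sizes$n_chr),
                                               length(hgenes))),
                    tss = sample(5e5:1.995e8, length(hgenes)))
  # planted cis effects: causal-set genes get an eSNP, which is also a GWAS
  # enriched SNP (inherited-risk signal rides on the causal set)
  cis_genes <- utils::head(causal_h$human_ids, sizes$n_cis)
  cis <- do.call(rbind, lapply(cis_genes, function(g) {
    row <- tss[tss$gene == g, ]
    cand <- snp_table[snp_table$chr == row$chr &
                        abs(snp_table$pos - row$tss) <= config$cis_window, ]
    if (!nrow(cand)) return(NULL)
    data.frame(gene = g, snp = cand$snp[1], effect = sizes$cis_effect)
  }))
  # LD blocks around each planted eSNP
  blocks <- lapply(cis$snp, function(s) {
    i <- match(s, snp_table$snp)
    ch <- snp_table$chr[i]
    members <- snp_table$snp[snp_table$chr == ch][
      seq(match(s, snp_table$snp[snp_table$chr == ch]),
          length.out = sizes$block_size)]
    list(snps = members[!is.na(members)], r2 = sizes$block_r2)
  })
  enriched <- unique(unlist(lapply(blocks, `[[`, "snps")))
  gtruth <- genotype_truth(snp_table, blocks, cis, tss,
                           gwas_enriched_snps = enriched,
                           p_hit = sizes$p_hit,
                           cis_window = config$cis_window)
  sim_g <- simulate_genotypes_gwas(gtruth, sizes$n_individuals,
                                   derive_seed(config$seed, "genotypes"))
  emit("simulate", function(p) write_gwas(sim_g$gwas, p), "gwas_summary.tsv")

  esnp_in <- intersect(causal_h$human_ids, rownames(sim_g$expr))
  esnps <- detect_cis_esnps(sim_g$expr, sim_g$dosage, tss,
                            sim_g$gwas[, c("snp", "chr", "pos", "maf")],
                            gene_ids = esnp_in,
                            cis_window = config$cis_window,
                            fdr = config$esnp_fdr)
  causal_exp <- expand_by_ld(esnps, sim_g$dosage,
                             sim_g$gwas[, c("snp", "chr", "pos", "maf")],
                             r2_threshold = config$r2_threshold,
                             ld_window = config$ld_window)
  esnps_re <- detect_cis_esnps(sim_g$expr, sim_g$dosage, tss,
                               sim_g$gwas[, c("snp", "chr", "pos", "maf")],
                               gene_ids = intersect(reactive_h$human_ids,
                                                    rownames(sim_g$expr)),
                               cis_window = config$cis_window,
                               fdr = config$esnp_fdr)
  reactive_exp <- subtract_overlap(
    expand_by_ld(esnps_re, sim_g$dosage,
                 sim_g$gwas[, c("snp", "chr", "pos", "maf")],
                 r2_threshold = config$r2_threshold,
                 ld_window = config$ld_window),
    causal_exp)
  emit("enrich", function(p) write_snp_set(causal_exp, p),
       "causal_expanded_snps.tsv")
  emit("enrich", function(p) write_snp_set(reactive_exp, p),
       "reactive_expanded_snps.tsv")
  enr <- list()
  for (nm in c("causal", "reactive")) {
    xs <- if (nm == "causal") causal_exp else reactive_exp
    if (nrow(xs)) {
      rnd <- sample_matched_sets(xs, sim_g$gwas[, c("snp", "chr", "maf")],
                                 n_sets = config$n_random_sets,
                                 maf_min = config$maf_min,
                                 seed = derive_seed(config$seed,
                                                    paste0("null-", nm)))
      enr[[nm]] <- compute_fold_enrichment(xs, rnd, sim_g$gwas,
                                           alpha = config$alpha)
    }
  }
  summary$enrichment <- lapply(enr, unclass)
  emit("enrich", function(p)
    jsonlite::write_json(summary$enrichment, p, auto_unbox = TRUE,
                         digits = NA), "enrichment.json")

  ## -- CLR TF network on the macrophage panel -------------------------------
  tf_ids <- sprintf("TF%02d", seq_len(sizes$n_tf))
  targets <- sprintf("TG%03d", seq_len(sizes$n_tf * sizes$targets_per_tf))
  edge_list <- data.frame(tf = rep(tf_ids, each = sizes$targets_per_tf),
                          target = targets, beta = sizes$beta)
  ptruth <- macrophage_panel_truth(
    tf_ids, edge_list, noise_sd = sizes$clr_noise_sd,
    n_samples = sizes$n_profiles,
    background_genes = sprintf("BG%03d", seq_len(sizes$panel_extra)))
  mac <- simulate_macrophage_expression(ptruth,
                                        derive_seed(config$seed, "macrophage"))
  scores <- clr_transform(compute_similarity(mac$expr))
  ep <- edge_pvalues(scores, "analytic")
  net <- build_tf_network(scores, ep, tf_ids,
                          retain_fraction = config$retain_fraction)
  hubs <- rank_master_regulators(net, top_k = 5L)
  emit("network", function(p) write_network(net, sub("\\.sif$", "", p)),
       "tf_network.sif")
  emit("network", function(p)
    utils::write.table(hubs, p, sep = "\t", quote = FALSE,
                       row.names = FALSE), "hubs.tsv")
  summary$network <- list(edges = nrow(net$edges),
                          member_count = net$member_count,
                          p_threshold = net$p_threshold)
  summary$hubs <- as.data.frame(hubs)

  ## -- perturbation screen on the top hub -----------------------------------
  top_tf <- hubs$tf[1]
  members <- setdiff(net$nodes$gene[net$nodes$degree > 0], top_tf)
  neighbors <- unique(c(net$edges$partner[net$edges$tf == top_tf],
                        net$edges$tf[net$edges$partner == top_tf]))
  set.seed(derive_seed(config$seed, "screen-design"))
  filler <- sprintf("FIL%04d", seq_len(sizes$screen_panel_size))
  panel <- utils::head(unique(c(top_tf, members, filler)),
                       sizes$screen_panel_size)
  hit_pool <- intersect(neighbors, panel)
  hits <- sample(hit_pool, min(sizes$screen_hits, length(hit_pool)))
  extra <- sample(setdiff(panel, c(hits, members, top_tf)),
                  sizes$screen_extra)
  affected_truth <- data.frame(
    gene = c(hits, extra),
    lfc = sizes$screen_lfc * sample(c(-1, 1), length(hits) + length(extra),
                                    replace = TRUE))
  struth <- perturbation_truth(top_tf, panel,
                               knockdown_fraction = sizes$kd_fraction,
                               affected_genes = affected_truth,
                               ce_shift = sizes$ce_shift)
  scr <- simulate_perturbation_screen(struth, sizes$screen_reps,
                                      derive_seed(config$seed, "screen"),
                                      ce_sd = sizes$ce_sd)
  called <- knockdown_de(scr$control, scr$knockdown, panel,
                         fdr = config$knockdown_fdr)
  netmem <- intersect(members, panel)
  frac <- affected_network_fraction(called, netmem)
  spec_p <- hypergeometric_specificity(M = length(panel),
                                       K = length(netmem),
                                       X = length(called$affected),
                                       x = frac$x)
  ce_ctrl <- scr$ce$ce[scr$ce$arm == "control"]
  ce_kd <- scr$ce$ce[scr$ce$arm == "knockdown"]
  ce <- ce_change(data.frame(total_chol = ce_ctrl, free_chol = 0,
                             protein = 1),
                  data.frame(total_chol = ce_kd, free_chol = 0, protein = 1))
  kd_eff <- 2^(mean(scr$knockdown[top_tf, ]) - mean(scr$control[top_tf, ]))
  summary$screen <- list(target = top_tf, n_affected = length(called$affected),
                         x = frac$x, K = length(netmem),
                         percent = frac$percent, specificity_p = spec_p,
                         knockdown_relative_expression = kd_eff,
                         ce_percent_change = ce$percent_change, ce_p = ce$p)
  emit("perturb", function(p)
    jsonlite::write_json(summary$screen, p, auto_unbox = TRUE, digits = NA),
    "screen_result.json")

  ## -- phenotype ------------------------------------------------------------
  hm <- default_histology_means()
  hist_sds <- hm
  hist_sds[, -1] <- 0.25 * hm[, -1] + 0.05   # spread scales with the mean
  hist <- simulate_histology(hm, group_sds = hist_sds[, -1],
                             n_mice = sizes$hist_n_mice,
                             missing_rate = sizes$hist_missing_rate,
                             seed = derive_seed(config$seed, "histology"))
  emit("phenotype", function(p) write_histology(hist, p), "histology.tsv")
  imp <- impute_missing(hist)
  scores_h <- plaque_stability_score(imp$table)
  summ <- stability_summary(scores_h)
  grp <- function(g) scores_h$normalized[scores_h$group == g &
                                           !scores_h$undefined]
  cmp <- group_compare(grp("pcl_20wk"), grp("before"))
  cmp10 <- group_compare(grp("pcl_10wk"), grp("before"))
  summary$phenotype <- list(
    stability = summ,
    before_vs_10wk_p = cmp10$p,
    before_vs_20wk_p = cmp$p,
    n_imputed = nrow(imp$log),
    cholesterol_percent_change = percent_change(254, 11.0))
  emit("phenotype", function(p)
    utils::write.table(format(as.data.frame(scores_h), digits = 15,
                              trim = TRUE),
                       p, sep = "\t", quote = FALSE, row.names = FALSE),
    "stability_scores.tsv")

  ## -- summary + manifest ---------------------------------------------------
  sum_path <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary, sum_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  written <- c(written, sum_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pclnet")),
    config = unclass(config),
    stage_seeds = stats::setNames(
      lapply(c("design", "timecourse", "orthologs", "genotype-design",
               "genotypes", "null-causal", "null-reactive", "macrophage",
               "screen-design", "screen", "histology"),
             function(s) derive_seed(config$seed, s)),
      c("design", "timecourse", "orthologs", "genotype-design", "genotypes",
        "null-causal", "null-reactive", "macrophage", "screen-design",
        "screen", "histology")),
    outputs = as.list(tools::md5sum(sort(written))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  summary$manifest <- file.path(outdir, "manifest.json")
  invisible(summary)
}
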