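# Stage-specific differential-expression gene sets, ortholog mapping and
# cross-stage overlaps.
#
# Two FDR routes are offered.  The Benjamini-Hochberg route controls the tail
# FDR of the member list.  The empirical-null local-fdr route fits a Normal
# null to the probit-transformed Welch statistics by central matching and a
# smooth mixture density by Lindsey's method (Poisson regression of histogram
# counts on a natural spline), then keeps genes with
# local fdr = pi0 * f0(z) / f(z) below the threshold.  The local route is the
# default for the mouse lesion contrasts.

#' Differential-expression configuration
#'
#' @param test only `"welch"` (unequal-variance two-sample statistic) is
#'   implemented; the field is kept explicit because the choice is a
#'   documented decision, not a given.
#' @param fdr_method `"efron_local"` (empirical-null local fdr, the default
#'   for the mouse lesion contrasts) or `"bh"` (Benjamini-Hochberg).
#' @param fdr_threshold membership threshold in (0,1); default 0.30 for the
#'   lesion contrasts.
#' @param exclude_samples sample ids to drop before testing (outlier handling
#'   is a config decision, never automated); every exclusion is recorded on
#'   the result.
#' @return A `de_config` object.
#' @export
de_config <- function(test = "welch",
                      fdr_method = c("efron_local", "bh"),
                      fdr_threshold = 0.30,
                      exclude_samples = character()) {
  test <- match.arg(test)
  fdr_method <- match.arg(fdr_method)
  if (fdr_threshold <= 0 || fdr_threshold >= 1)
    stop("fdr_threshold must lie in (0, 1)")
  structure(list(test = test, fdr_method = fdr_method,
                 fdr_threshold = fdr_threshold,
                 exclude_samples = exclude_samples),
            class = "de_config")
}

# Empirical-null local fdr for probit z-scores.
# Central matching: null N(median, IQR/1.349); mixture density by Lindsey's
# method (Poisson GLM on bin counts over a natural spline);
# pi0 = min(1, f(delta)/f0(delta)).  The density entering the ratio is
# penalised by its sampling uncertainty (lower 2-SE bound on the link
# scale): in sparse tail bins, where the raw fit can overshoot on one or two
# stray scores, the penalty drives the fdr back to 1, while genuine signal
# bumps carry enough counts that the penalty is negligible.
local_fdr <- function(z, df_spline = 7, n_bins = 90, se_penalty = 2) {
  stopifnot(length(z) >= 50)
  delta <- stats::median(z)
  sigma <- stats::IQR(z) / (2 * stats::qnorm(0.75))
  if (sigma <= 0) sigma <- 1
  rng <- range(z)
  pad <- 0.01 * diff(rng) + 1e-8
  breaks <- seq(rng[1] - pad, rng[2] + pad, length.out = n_bins + 1)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  counts <- as.vector(table(cut(z, breaks, include.lowest = TRUE)))
  fit <- suppressWarnings(
    stats::glm(counts ~ splines::ns(mids, df = df_spline),
               family = stats::poisson()))
  width <- diff(breaks)[1]
  norm <- length(z) * width
  pr <- stats::predict(fit, newdata = data.frame(mids = z), type = "link",
                       se.fit = TRUE)
  f_pen <- pmax(exp(pr$fit - se_penalty * pr$se.fit) / norm, 1e-12)
  f_center <- pmax(exp(stats::predict(fit, newdata = data.frame(mids = delta),
                                      type = "link")) / norm, 1e-12)
  f0 <- function(x) stats::dnorm(x, delta, sigma)
  pi0 <- min(1, f_center / f0(delta))
  fdr <- pmin(1, pi0 * f0(z) / f_pen)
  list(fdr = fdr, delta = delta, sigma = sigma, pi0 = pi0)
}

#' Differential expression between two sample groups
#'
#' Computes a per-gene Welch statistic and two-sided p, applies the
#' configured FDR procedure, and returns the genes passing
#' `fdr < fdr_threshold` with their direction.  Genes with zero variance in
#' both groups are tested against a variance floor and flagged.
#'
#' @param expr genes x samples numeric matrix (log2 scale).
#' @param group_a_samples,group_b_samples disjoint character vectors of
#'   column names (each of length >= 2 after exclusions).  Direction `up`
#'   means higher in group b (the "after" group in stage contrasts).
#' @param config a [de_config()].
#' @return A `gene_set` object: list with `table` (gene, statistic, p, fdr,
#'   direction, flagged), `members`, `stage`, `contrast`, `config`, and the
#'   null-fit parameters when the local-fdr route was used.
#' @export
differential_expression <- function(expr, group_a_samples, group_b_samples,
                                    config = de_config()) {
  stopifnot(is.matrix(expr), inherits(config, "de_config"))
  group_a_samples <- setdiff(group_a_samples, config$exclude_samples)
  group_b_samples <- setdiff(group_b_samples, config$exclude_samples)
  if (length(intersect(group_a_samples, group_b_samples)))
    stop("sample groups overlap")
  if (length(group_a_samples) < 2 || length(group_b_samples) < 2)
    stop("each group needs >= 2 samples")
  missing <- setdiff(c(group_a_samples, group_b_samples), colnames(expr))
  if (length(missing))
    stop("samples not in expression matrix: ", paste(missing, collapse = ", "))
  w <- welch_rows(expr[, group_b_samples, drop = FALSE],
                  expr[, group_a_samples, drop = FALSE])
  tab <- data.frame(gene = rownames(expr), statistic = w$statistic,
                    p = w$p, flagged = w$flagged,
                    direction = ifelse(w$statistic >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  null_fit <- NULL
  if (config$fdr_method == "bh" || nrow(tab) < 50) {
    tab$fdr <- bh_adjust(tab$p)
  } else {
    # probit transform of the one-sided tail keeps the sign of the statistic
    pz <- pmin(pmax(stats::pt(w$statistic, w$df), 1e-15), 1 - 1e-15)
    lf <- local_fdr(stats::qnorm(pz))
    tab$fdr <- lf$fdr
    null_fit <- lf[c("delta", "sigma", "pi0")]
  }
  members <- tab$gene[tab$fdr < config$fdr_threshold]
  structure(list(table = tab, members = members, stage = NA_character_,
                 contrast = NA_character_, config = config,
                 excluded_samples = config$exclude_samples,
                 null_fit = null_fit),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set: %s / %s - %d members of %d genes (%s, fdr < %g)\n",
              x$stage, x$contrast, length(x$members), nrow(x$table),
              x$config$fdr_method, x$config$fdr_threshold))
  invisible(x)
}

#' Define the PCL-responsive and regression-reactive gene sets for one stage
#'
#' The PCL-responsive set contrasts high-cholesterol controls at the stage
#' with samples taken immediately after plasma cholesterol lowering; the
#' regression-reactive set contrasts immediately-after with 10-weeks-after
#' samples.
#'
#' @param expr genes x samples matrix.
#' @param annotations data.frame with `sample_id`, `timepoint`, `cell`
#'   (`control`, `post_pcl`, `regression_10wk`).
#' @param stage a timepoint label present in `annotations`.
#' @param config a [de_config()].
#' @return A list with `pcl_responsive` and `regression_reactive`
#'   [differential_expression()] results, stage/contrast fields filled in.
#' @export
define_stage_gene_sets <- function(expr, annotations, stage,
                                   config = de_config()) {
  stop_if_not_named_df(annotations, c("sample_id", "timepoint", "cell"),
                       "annotations")
  stage <- as.character(stage)
  pick <- function(cell) {
    s <- annotations$sample_id[annotations$timepoint == stage &
                                 annotations$cell == cell]
    if (!length(s))
      stop(sprintf("no samples for stage %s, cell '%s'", stage, cell))
    s
  }
  ctrl <- pick("control"); post <- pick("post_pcl")
  reg <- pick("regression_10wk")
  pcl <- differential_expression(expr, ctrl, post, config)
  rea <- differential_expression(expr, post, reg, config)
  pcl$stage <- rea$stage <- stage
  pcl$contrast <- "pcl_responsive"
  rea$contrast <- "regression_reactive"
  list(pcl_responsive = pcl, regression_reactive = rea)
}

#' Map a gene set to human orthologs
#'
#' @param gene_set a `gene_set` object or a character vector of gene ids.
#' @param table ortholog table: data.frame with `mouse_id`, `human_id`
#'   (1:1, 1:many and many:1 rows are all honoured; many:1 collapses are
#'   deduplicated).
#' @return A list with `human_ids` (deduplicated, in first-seen order),
#'   `n_unmapped`, and `unmapped` (the input genes without any table row).
#' @export
map_orthologs <- function(gene_set, table) {
  stop_if_not_named_df(table, c("mouse_id", "human_id"), "ortholog table")
  if (!nrow(table)) stop("ortholog table is empty")
  ids <- if (inherits(gene_set, "gene_set")) gene_set$members else gene_set
  hit <- table[table$mouse_id %in% ids &
                 nzchar(table$human_id) & !is.na(table$human_id), ]
  unmapped <- setdiff(ids, hit$mouse_id)
  list(human_ids = unique(hit$human_id),
       n_unmapped = length(unmapped),
       unmapped = unmapped)
}

#' Intersection-region counts and unique fractions for several gene sets
#'
#' Computes the count of every membership region (as in a Venn diagram) and,
#' per set, the fraction of its members unique to it, rounded to whole
#' percent.
#'
#' @param sets named list (>= 2) of `gene_set` objects or character vectors.
#' @return A list with `regions` (data.frame `region`, `count`) and
#'   `unique_percent` (named vector, whole percents).
#' @export
overlap_fractions <- function(sets) {
  if (length(sets) < 2) stop("need at least two sets")
  ids <- lapply(sets, function(s)
    unique(if (inherits(s, "gene_set")) s$members else s))
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(ids) <- paste0("set", seq_along(ids))
  universe <- unique(unlist(ids))
  memb <- vapply(ids, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1,
                                             dimnames = list(NULL, names(ids)))
  region <- apply(memb, 1, function(r)
    paste(names(ids)[r], collapse = "&"))
  regions <- as.data.frame(table(region), stringsAsFactors = FALSE)
  names(regions) <- c("region", "count")
  uniq <- vapply(names(ids), function(nm) {
    n <- length(ids[[nm]])
    if (n == 0) return(NA_real_)
    only <- sum(memb[, nm] & rowSums(memb) == 1L)
    round_half_away(100 * only / n)
  }, numeric(1))
  list(regions = regions, unique_percent = uniq)
}

#' Write gene sets to a GMT file
#'
#' One line per set: `stage_contrast<TAB>description<TAB>member...`.
#'
#' @param sets list of `gene_set` objects.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    stopifnot(inherits(s, "gene_set"))
    nm <- paste(s$stage, s$contrast, sep = "_")
    paste(c(nm, sprintf("fdr<%g", s$config$fdr_threshold), s$members),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a gene set's full statistics table as TSV
#'
#' @param set a `gene_set`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_gene_set_tsv <- function(set, path) {
  stopifnot(inherits(set, "gene_set"))
  tab <- set$table
  tab$stage <- set$stage
  tab$contrast <- set$contrast
  tab$member <- tab$gene %in% set$members
  utils::write.table(format(tab, digits = 15, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ortholog table TSV (columns mouse_id, human_id, source)
#'
#' @param path TSV path with a header row.
#' @return data.frame with the three columns.
#' @export
read_ortholog_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stop_if_not_named_df(tab, c("mouse_id", "human_id"), "ortholog table file")
  if (any(!nzchar(tab$mouse_id)))
    stop("ortholog table contains empty mouse identifiers")
  tab
}
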