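# Context likelihood of relatedness (CLR) TF-regulatory network inference.
#
# Similarity is |Pearson r| between expression profiles.  For each pair the
# similarity is converted to background-corrected z-scores against the two
# genes' own similarity distributions (rows of M, diagonal excluded, clipped
# at zero), combined as the Euclidean joint score z_ij = sqrt(z_i^2 + z_j^2).
# Two edge-significance modes are offered: the parameter-free analytic tail
# exp(-z^2/2) (the Rayleigh tail of the joint of two standard scores) and a
# permutation mode that is the empirical ground truth for calibration.

#' Pairwise co-expression similarity matrix
#'
#' @param expr genes x samples matrix (>= 4 samples).
#' @param gene_subset genes to include (default all rows).
#' @return A `similarity_matrix`: list with `M` (|Pearson r|, diagonal `NA`
#'   and excluded from all statistics), `genes`, `constant_genes` (flagged
#'   genes with zero variance whose similarities are set to 0).
#' @export
compute_similarity <- function(expr, gene_subset = rownames(expr)) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 4) stop("need >= 4 samples")
  missing <- setdiff(gene_subset, rownames(expr))
  if (length(missing))
    stop("genes not in expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  x <- expr[gene_subset, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  constant <- rownames(x)[sds == 0]
  M <- suppressWarnings(abs(stats::cor(t(x))))
  M[is.na(M)] <- 0
  M[constant, ] <- 0
  M[, constant] <- 0
  diag(M) <- NA_real_
  structure(list(M = M, genes = gene_subset, constant_genes = constant),
            class = "similarity_matrix")
}

#' CLR background correction and joint scores
#'
#' For pair (i, j): `z_i = max(0, (M[i,j] - mu_i) / sd_i)` with `mu_i`,
#' `sd_i` the mean and SD of row i (diagonal excluded); `z_j` analogous for
#' row j; the joint score is `z_ij = sqrt(z_i^2 + z_j^2)`.  Rows with zero
#' background SD contribute `z = 0` and are flagged.
#'
#' @param sim a [compute_similarity()] result.
#' @return A `clr_scores` object: list with `Z` (symmetric joint-score
#'   matrix, diagonal `NA`), `genes`, `flat_rows`.
#' @export
clr_transform <- function(sim) {
  stopifnot(inherits(sim, "similarity_matrix"))
  M <- sim$M
  mu <- rowMeans(M, na.rm = TRUE)
  sd_ <- apply(M, 1, stats::sd, na.rm = TRUE)
  flat <- rownames(M)[is.na(sd_) | sd_ == 0]
  sd_[is.na(sd_) | sd_ == 0] <- Inf   # z contribution 0 for flat backgrounds
  Zi <- pmax((M - mu) / sd_, 0)        # row-referenced z for each entry
  Z <- sqrt(Zi^2 + t(Zi)^2)
  diag(Z) <- NA_real_
  structure(list(Z = Z, genes = sim$genes, flat_rows = flat),
            class = "clr_scores")
}

#' Edge significance for CLR joint scores
#'
#' @param scores a [clr_transform()] result.
#' @param method `"analytic"` (`edge_p = exp(-z^2/2)`, monotone decreasing in
#'   the joint score, parameter-free) or `"permutation"` (empirical upper
#'   tail of the joint score over expression matrices whose samples are
#'   permuted independently per gene, pooled across all pairs).
#' @param expr expression matrix (required for the permutation mode; must
#'   cover `scores$genes`).
#' @param n_perm target number of pooled null draws for the permutation mode
#'   (resolution is `1/(n_null + 1)`; default 1000).
#' @param seed seed for the permutation mode.
#' @return Symmetric matrix of per-pair edge p-values (diagonal `NA`).
#' @export
edge_pvalues <- function(scores, method = c("analytic", "permutation"),
                         expr = NULL, n_perm = 1000L, seed = NULL) {
  stopifnot(inherits(scores, "clr_scores"))
  method <- match.arg(method)
  Z <- scores$Z
  if (method == "analytic") {
    P <- exp(-Z^2 / 2)
    diag(P) <- NA_real_
    return(P)
  }
  if (is.null(expr)) stop("permutation mode needs the expression matrix")
  if (!is.null(seed)) set.seed(seed)
  g <- scores$genes
  x <- expr[g, , drop = FALSE]
  npairs <- length(g) * (length(g) - 1) / 2
  rounds <- max(1L, ceiling(n_perm / npairs))
  null_z <- numeric(0)
  for (b in seq_len(rounds)) {
    xp <- t(apply(x, 1, sample))
    rownames(xp) <- rownames(x)
    Zp <- clr_transform(compute_similarity(xp))$Z
    null_z <- c(null_z, Zp[upper.tri(Zp)])
  }
  n_null <- length(null_z)
  null_sorted <- sort(null_z)
  obs <- Z[upper.tri(Z)]
  # count of null >= obs via binary search on the sorted null
  ge <- n_null - findInterval(obs - 1e-12, null_sorted)
  pvec <- (1 + ge) / (n_null + 1)
  P <- matrix(NA_real_, nrow(Z), ncol(Z), dimnames = dimnames(Z))
  P[upper.tri(P)] <- pvec
  P[lower.tri(P)] <- t(P)[lower.tri(P)]
  P
}

#' Build the thresholded TF-regulatory network
#'
#' Candidate interactions are all (TF, gene) pairs within `gene_set` with
#' distinct endpoints (TF-TF pairs counted once).  Exactly the
#' `retain_fraction` of candidates with the smallest edge p-values is kept —
#' the most probable interactions — with boundary ties resolved
#' deterministically by (edge p, tf, partner) order.  The largest retained
#' edge p is reported as the network's p threshold.
#'
#' @param scores a [clr_transform()] result.
#' @param edge_p matrix from [edge_pvalues()].
#' @param tf_list character vector of TF gene ids.
#' @param gene_set genes defining the network universe (default all scored
#'   genes).
#' @param retain_fraction fraction of candidate interactions to keep
#'   (default 0.5).
#' @return A `tf_network`: list with `edges` (data.frame `tf`, `partner`,
#'   `z`, `edge_p`), `nodes` (`gene`, `is_tf`, `degree`), `p_threshold`,
#'   `member_count` (nodes with degree >= 1), `retained_fraction`,
#'   `n_candidates`.
#' @export
build_tf_network <- function(scores, edge_p, tf_list,
                             gene_set = scores$genes,
                             retain_fraction = 0.5) {
  stopifnot(inherits(scores, "clr_scores"))
  gene_set <- intersect(gene_set, scores$genes)
  tfs <- intersect(tf_list, gene_set)
  if (!length(tfs)) stop("no TFs present in the gene set")
  cand <- expand.grid(tf = tfs, partner = gene_set,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cand <- cand[cand$tf != cand$partner, ]
  # TF-TF pairs appear twice in the grid; orient tf = smaller id and dedupe
  both_tf <- cand$partner %in% tfs
  flip <- both_tf & cand$tf > cand$partner
  tmp <- cand$tf[flip]; cand$tf[flip] <- cand$partner[flip]
  cand$partner[flip] <- tmp
  cand <- cand[!duplicated(cand[, c("tf", "partner")]), ]
  idx <- cbind(match(cand$tf, rownames(edge_p)),
               match(cand$partner, colnames(edge_p)))
  cand$edge_p <- edge_p[idx]
  cand$z <- scores$Z[cbind(match(cand$tf, rownames(scores$Z)),
                           match(cand$partner, colnames(scores$Z)))]
  n_cand <- nrow(cand)
  k <- floor(retain_fraction * n_cand + 1e-9)
  if (k < 1) {
    edges <- cand[0, ]
    p_threshold <- NA_real_
  } else {
    # exactly k edges; ties at the boundary resolved deterministically by
    # (edge_p, tf, partner) lexicographic order (z = 0 pairs all share
    # edge_p = 1, so a keep-all-ties rule would degenerate)
    ord <- order(cand$edge_p, cand$tf, cand$partner)
    p_threshold <- cand$edge_p[ord[k]]
    edges <- cand[ord[seq_len(k)], ]
  }
  edges <- edges[order(edges$tf, edges$partner), ]
  rownames(edges) <- NULL
  degree <- table(c(edges$tf, edges$partner))
  nodes <- data.frame(gene = gene_set,
                      is_tf = gene_set %in% tfs,
                      degree = as.integer(degree[gene_set]),
                      stringsAsFactors = FALSE)
  nodes$degree[is.na(nodes$degree)] <- 0L
  structure(list(edges = edges, nodes = nodes, p_threshold = p_threshold,
                 member_count = sum(nodes$degree >= 1L),
                 retained_fraction = nrow(edges) / max(n_cand, 1L),
                 n_candidates = n_cand),
            class = "tf_network")
}

#' @export
print.tf_network <- function(x, ...) {
  cat(sprintf(paste0("tf_network: %d edges over %d member genes ",
                     "(p threshold %.3g, retained %.1f%% of %d candidates)\n"),
              nrow(x$edges), x$member_count, x$p_threshold,
              100 * x$retained_fraction, x$n_candidates))
  invisible(x)
}

#' Rank hub TFs as candidate master regulators
#'
#' TFs are ranked by degree (connections) in the thresholded network,
#' descending, ties broken by gene id so the ranking is deterministic.
#'
#' @param network a [build_tf_network()] result.
#' @param top_k number of hubs to report (truncated to the TF count).
#' @return A `hub_table` data.frame with `tf`, `connections`.
#' @export
rank_master_regulators <- function(network, top_k = 5L) {
  stopifnot(inherits(network, "tf_network"))
  if (!nrow(network$edges)) {
    warning("edgeless network: no hubs to rank")
    return(structure(data.frame(tf = character(), connections = integer()),
                     class = c("hub_table", "data.frame")))
  }
  tfs <- network$nodes[network$nodes$is_tf & network$nodes$degree > 0, ]
  tfs <- tfs[order(-tfs$degree, tfs$gene), ]
  out <- data.frame(tf = tfs$gene, connections = tfs$degree,
                    stringsAsFactors = FALSE)
  out <- utils::head(out, top_k)
  rownames(out) <- NULL
  structure(out, class = c("hub_table", "data.frame"))
}
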