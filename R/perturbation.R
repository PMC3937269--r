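# siRNA knockdown-screen analysis on the fixed gene panel: affected-gene
# calls, network-affected fractions, hypergeometric specificity, comparative
# Ct normalisation, and cholesterol-ester accumulation changes.

#' Affected genes after an siRNA knockdown
#'
#' Per-gene Welch test between the control and knockdown replicates over the
#' panel, Benjamini-Hochberg across the panel, affected =
#' `FDR < fdr` with direction.  The default threshold is 0.1 (0.05 is the
#' config value used for the advanced-lesion network screen).
#'
#' @param control_expr,kd_expr panel x replicates matrices (>= 2 replicates
#'   each).
#' @param panel character vector of panel gene ids; both matrices must cover
#'   the full panel.
#' @param fdr BH threshold (default 0.1).
#' @return A `screen_result`: list with `affected` (character), `table`
#'   (gene, statistic, p, fdr, direction), `fdr`.
#' @export
knockdown_de <- function(control_expr, kd_expr, panel, fdr = 0.1) {
  stopifnot(is.matrix(control_expr), is.matrix(kd_expr))
  for (nm in list(c("control", "control_expr"), c("knockdown", "kd_expr"))) {
    m <- get(nm[2])
    miss <- setdiff(panel, rownames(m))
    if (length(miss))
      stop(sprintf("panel genes missing from the %s matrix: %s", nm[1],
                   paste(utils::head(miss, 10), collapse = ", ")))
  }
  if (ncol(control_expr) < 2 || ncol(kd_expr) < 2)
    stop("need >= 2 replicates per arm")
  w <- welch_rows(kd_expr[panel, , drop = FALSE],
                  control_expr[panel, , drop = FALSE])
  tab <- data.frame(gene = panel, statistic = w$statistic, p = w$p,
                    fdr = bh_adjust(w$p),
                    direction = ifelse(w$statistic >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  structure(list(affected = tab$gene[tab$fdr < fdr], table = tab, fdr = fdr),
            class = "screen_result")
}

#' Fraction of a network perturbed by a knockdown
#'
#' @param affected character vector of affected genes (or a `screen_result`).
#' @param network_members the network's gene members (must be on the panel).
#' @param K network size; defaults to `length(network_members)`.
#' @return A list with `x` (overlap count) and `percent`
#'   (`round(100 * x / K)`, half away from zero).
#' @export
#' @examples
#' affected_network_fraction(paste0("g", 1:15), paste0("g", 1:53))$percent # 28
affected_network_fraction <- function(affected, network_members,
                                      K = length(network_members)) {
  if (inherits(affected, "screen_result")) affected <- affected$affected
  if (K == 0) stop("network is empty (K = 0)")
  x <- length(intersect(affected, network_members))
  list(x = x, percent = round_half_away(100 * x / K))
}

#' Hypergeometric specificity of a knockdown for a network
#'
#' When `X` of the `M` panel genes are affected by silencing a TF, the
#' probability that `x` or more of them fall inside the TF's time-point
#' network of size `K` is the upper hypergeometric tail
#' \deqn{P = \sum_{k=x}^{\min(X,K)} \binom{K}{k}\binom{M-K}{X-k} / \binom{M}{X}.}
#'
#' @param M panel size (population; 673 for the screen panel).
#' @param K network size within the panel (53, 185 or 379 for the early,
#'   mature, advanced networks).
#' @param X number of panel genes affected by the silencing.
#' @param x observed overlap with the network.
#' @return The upper-tail probability.
#' @export
#' @examples
#' hypergeometric_specificity(M = 10, K = 4, X = 3, x = 2)  # 1/3
hypergeometric_specificity <- function(M, K, X, x) {
  vals <- c(M = M, K = K, X = X, x = x)
  if (any(vals != round(vals)) || any(vals < 0))
    stop("M, K, X, x must be non-negative integers")
  if (X > M) stop("cannot draw more genes than the panel holds (X > M)")
  if (K > M) stop("network larger than the panel (K > M)")
  if (x > min(X, K)) return(0)
  if (x == 0) return(1)
  stats::phyper(x - 1, K, M - K, X, lower.tail = FALSE)
}

#' Relative expression by the comparative Ct method
#'
#' @param target_ct,reference_ct cycle-threshold values of the target and the
#'   endogenous reference in the test sample.
#' @param calibrator_delta `(target - reference)` Ct difference of the
#'   calibrator sample.
#' @return Relative expression `2^(-ddCt)` with
#'   `ddCt = (target_ct - reference_ct) - calibrator_delta`.
#' @export
#' @examples
#' comparative_ct(21, 20, 0)  # one extra cycle: 0.5
comparative_ct <- function(target_ct, reference_ct, calibrator_delta = 0) {
  if (!all(is.finite(c(target_ct, reference_ct, calibrator_delta))))
    stop("Ct values must be finite")
  2^(-((target_ct - reference_ct) - calibrator_delta))
}

#' Cholesterol-ester accumulation change after a knockdown
#'
#' Per replicate, CE = (total cholesterol - free cholesterol) / protein.
#' Both arms are rescaled so the control mean is 100; the percent change is
#' the knockdown mean minus 100, rounded half away from zero (printed-table
#' style: +12, -17), with a two-sided Welch p.
#'
#' @param control,kd data.frames with columns `total_chol`, `free_chol`,
#'   `protein` (one row per replicate, >= 3 per arm).
#' @return A `ce_result`: list with `control_rel`, `kd_rel` (relative CE
#'   values), `percent_change`, `p`, `negative_ce` flag (negative CE after
#'   subtraction, retained).
#' @export
ce_change <- function(control, kd) {
  for (d in list(control, kd))
    stop_if_not_named_df(d, c("total_chol", "free_chol", "protein"),
                         "each CE table")
  if (nrow(control) < 3 || nrow(kd) < 3)
    stop("need >= 3 replicates per arm")
  if (any(control$protein <= 0) || any(kd$protein <= 0))
    stop("protein concentrations must be > 0")
  ce <- function(d) (d$total_chol - d$free_chol) / d$protein
  ce_c <- ce(control); ce_k <- ce(kd)
  negative_ce <- any(c(ce_c, ce_k) < 0)
  scale <- 100 / mean(ce_c)
  ce_c <- ce_c * scale; ce_k <- ce_k * scale
  p <- if (stats::var(ce_c) == 0 && stats::var(ce_k) == 0) {
    if (mean(ce_c) == mean(ce_k)) 1 else 0
  } else stats::t.test(ce_k, ce_c)$p.value
  structure(list(control_rel = ce_c, kd_rel = ce_k,
                 percent_change = round_half_away(mean(ce_k) - 100),
                 p = p, negative_ce = negative_ce),
            class = "ce_result")
}
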