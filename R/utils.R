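# Internal helpers shared across modules.

#' Derive a stage seed from a global seed
#'
#' Every stochastic stage of the pipeline receives its own seed, derived
#' deterministically from the global seed and the stage name, so that
#' re-running one stage never perturbs another.
#'
#' @param global_seed integer global seed.
#' @param stage character stage name.
#' @return An integer seed in `[0, 2^31)`.
#' @export
#' @examples
#' derive_seed(1L, "network")
derive_seed <- function(global_seed, stage) {
  stopifnot(is.numeric(global_seed), length(global_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  codes <- utf8ToInt(stage)
  h <- (abs(as.numeric(global_seed)) %% 2147483647)
  for (k in codes) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

# Round half away from zero (printed tables use +12 / -17 style integers;
# base round() is banker's rounding).
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Vectorised Welch two-sample test over matrix rows.
# Returns statistic (a minus b orientation), df, p, and a flag for rows where
# a variance floor was needed (both group variances zero).
welch_rows <- function(a, b, var_floor = 1e-12) {
  a <- as.matrix(a); b <- as.matrix(b)
  na <- ncol(a); nb <- ncol(b)
  stopifnot(na >= 2, nb >= 2, nrow(a) == nrow(b))
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  flagged <- se2 < var_floor
  se2[flagged] <- var_floor
  stat <- (ma - mb) / sqrt(se2)
  # Welch-Satterthwaite df; degenerate rows get df = na + nb - 2
  num <- se2^2
  den <- (va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)
  df <- ifelse(den > 0, num / den, na + nb - 2)
  # rows with zero diff and zero variance: no evidence at all
  stat[flagged & abs(ma - mb) < sqrt(var_floor)] <- 0
  p <- 2 * stats::pt(-abs(stat), df)
  data.frame(statistic = stat, df = df, p = p, flagged = flagged,
             mean_diff = ma - mb, row.names = rownames(a))
}

# Benjamini-Hochberg adjusted p-values (thin wrapper, single call site).
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_if_not_named_df <- function(x, cols, what) {
  if (!is.data.frame(x) || !all(cols %in% names(x)))
    stop(sprintf("%s must be a data.frame with columns: %s",
                 what, paste(cols, collapse = ", ")), call. = FALSE)
  invisible(x)
}
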