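# Phenotype-level statistics: percent lipid changes, the plaque stability
# score with burden normalisation, group-mean imputation, and two-sided
# Welch comparisons between timepoints.

#' Percent change between two group means
#'
#' @param before_mean,after_mean group means; `before_mean` must be > 0.
#' @param digits decimals for reporting (default 1, the printed style); use
#'   `NULL` for full precision.
#' @return `100 * (after - before) / before`.
#' @export
#' @examples
#' percent_change(254, 11.0)  # -95.7: week-30 cholesterol, before vs 10wk after
percent_change <- function(before_mean, after_mean, digits = 1) {
  if (any(before_mean <= 0)) stop("before_mean must be > 0")
  out <- 100 * (after_mean - before_mean) / before_mean
  if (!is.null(digits)) out <- round_half_away(out, digits)
  out
}

#' Plaque stability scores with burden normalisation
#'
#' Raw score = (SM22a + collagen) / (CD68 + Oil-Red-O) stained-area
#' percentages; the normalised score divides by the mouse's lesion burden so
#' stability is assessed per mouse, not per plaque.  Mice with a zero
#' denominator get an undefined (NA) score, are flagged, and are excluded
#' from group summaries.
#'
#' @param records data.frame with columns `mouse_id`, `group`, `sm22`,
#'   `collagen`, `cd68`, `oro`, `burden` (percentages; burden > 0 for scored
#'   mice).
#' @return A `stability_scores` data.frame: the input plus `raw`,
#'   `normalized`, `undefined` (logical flag).
#' @export
#' @examples
#' plaque_stability_score(data.frame(mouse_id = "m1", group = "g",
#'   sm22 = 10, collagen = 10, cd68 = 5, oro = 5, burden = 4))
plaque_stability_score <- function(records) {
  fields <- c("mouse_id", "group", "sm22", "collagen", "cd68", "oro",
              "burden")
  stop_if_not_named_df(records, fields, "histology records")
  pct <- as.matrix(records[, c("sm22", "collagen", "cd68", "oro")])
  if (any(pct < 0 | pct > 100, na.rm = TRUE))
    stop("stained-area percentages must lie in [0, 100]")
  denom <- records$cd68 + records$oro
  undefined <- !is.na(denom) & denom == 0
  raw <- (records$sm22 + records$collagen) / denom
  raw[undefined] <- NA_real_
  bad_burden <- !is.na(records$burden) & records$burden <= 0
  normalized <- raw / records$burden
  normalized[bad_burden] <- NA_real_
  out <- records
  out$raw <- raw
  out$normalized <- normalized
  out$undefined <- undefined | bad_burden
  if (any(out$undefined))
    message(sum(out$undefined),
            " mouse/mice with undefined stability score excluded from summaries")
  structure(out, class = c("stability_scores", "data.frame"))
}

#' Group mean and SD of (normalised) stability scores
#'
#' @param scores a [plaque_stability_score()] result.
#' @param which `"normalized"` (default) or `"raw"`.
#' @return data.frame `group`, `mean`, `sd`, `n` (undefined scores excluded).
#' @export
stability_summary <- function(scores, which = c("normalized", "raw")) {
  which <- match.arg(which)
  ok <- scores[!scores$undefined & !is.na(scores[[which]]), ]
  agg <- do.call(rbind, lapply(split(ok[[which]], ok$group), function(v)
    data.frame(mean = mean(v), sd = stats::sd(v), n = length(v))))
  data.frame(group = rownames(agg), agg, row.names = NULL)
}

#' Impute missing histology cells
#'
#' Default strategy fills each missing cell with the group mean of the
#' observed values for that field (leaving observed+imputed group means
#' unchanged); the `"stochastic"` strategy draws from the group's fitted
#' Normal instead (seeded), a single-draw stand-in for multiple imputation.
#' Every imputed cell is logged.
#'
#' @param table histology data.frame (`mouse_id`, `group`, measurement
#'   columns).
#' @param strategy `"group_mean"` or `"stochastic"`.
#' @param seed seed for the stochastic strategy.
#' @param fields measurement columns to complete.
#' @return A list with `table` (completed) and `log` (data.frame `mouse_id`,
#'   `group`, `field`, `value`, `strategy`).
#' @export
impute_missing <- function(table, strategy = c("group_mean", "stochastic"),
                           seed = NULL,
                           fields = c("sm22", "collagen", "cd68", "oro",
                                      "burden")) {
  strategy <- match.arg(strategy)
  stop_if_not_named_df(table, c("mouse_id", "group", fields), "histology table")
  if (strategy == "stochastic") {
    if (is.null(seed)) stop("stochastic imputation needs a seed")
    set.seed(seed)
  }
  log <- list()
  for (g in unique(table$group)) {
    idx <- which(table$group == g)
    for (f in fields) {
      v <- table[[f]][idx]
      miss <- is.na(v)
      if (!any(miss)) next
      if (all(miss))
        stop(sprintf("group '%s', field '%s' is fully missing", g, f))
      mu <- mean(v[!miss])
      fill <- if (strategy == "group_mean") rep(mu, sum(miss)) else
        stats::rnorm(sum(miss), mu,
                     if (sum(!miss) > 1) stats::sd(v[!miss]) else 0)
      table[[f]][idx[miss]] <- fill
      log[[length(log) + 1L]] <- data.frame(
        mouse_id = table$mouse_id[idx[miss]], group = g, field = f,
        value = fill, strategy = strategy, stringsAsFactors = FALSE)
    }
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(mouse_id = character(), group = character(),
               field = character(), value = numeric(), strategy = character())
  list(table = table, log = log)
}

#' Two-sided Welch comparison of two groups
#'
#' @param values_a,values_b numeric vectors (>= 2 each).
#' @return A list with `p`, `difference` (mean a - mean b), `statistic`.
#'   When both groups have zero variance: `p = 1` if the means are equal,
#'   `p = 0` otherwise (flagged degenerate).
#' @export
group_compare <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("need >= 2 values per group")
  diff <- mean(values_a) - mean(values_b)
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0) {
    return(list(p = if (diff == 0) 1 else 0, difference = diff,
                statistic = if (diff == 0) 0 else sign(diff) * Inf,
                degenerate = TRUE))
  }
  tt <- stats::t.test(values_a, values_b)
  list(p = tt$p.value, difference = diff,
       statistic = unname(tt$statistic), degenerate = FALSE)
}
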