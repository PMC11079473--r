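# Cohort outcome statistics: responder classification (>50% seizure
# reduction at 1-year follow-up), subgroup response rates, odds ratios,
# Fisher exact / Wilcoxon / t tests, and region-level IED occurrence.
# The standard tests delegate to stats::; the tests' independent
# enumeration oracles live in the test suite.

#' Seizure reduction
#'
#' Percent reduction between the 3-month pre-implant seizure count and the
#' count in the 3 months before the 1-year follow-up. Worsening gives a
#' negative value.
#'
#' @param pre,post Seizure counts (>= 0).
#' @return Reduction in percent.
#' @export
seizure_reduction <- function(pre, post) {
  if (any(pre < 0) || any(post < 0)) stopf("seizure counts must be >= 0")
  if (any(pre == 0))
    stopf("seizure reduction is undefined for a zero pre-implant count")
  100 * (pre - post) / pre
}

#' Responder flag
#'
#' Strictly more than 50% seizure reduction; exactly 50% is a
#' non-responder.
#'
#' @param sr Seizure reduction in percent.
#' @return Logical.
#' @export
is_responder <- function(sr) sr > 50

#' Subgroup response rate
#'
#' Responders per subgroup size, in percent rounded half-up to an integer.
#'
#' @param responder Logical vector over the cohort.
#' @param subset Logical vector selecting the subgroup (default: all).
#' @param raw Return the unrounded percentage too?
#' @return Integer percent (or list with `percent`, `raw`, `n`, `k` when
#'   `raw = TRUE`).
#' @export
response_rate <- function(responder, subset = rep(TRUE, length(responder)),
                          raw = FALSE) {
  stopifnot(is.logical(responder), length(subset) == length(responder))
  n <- sum(subset)
  if (n == 0L) stopf("empty subgroup")
  k <- sum(responder & subset)
  p <- 100 * k / n
  if (raw) list(percent = round_half_up(p), raw = p, n = n, k = k)
  else round_half_up(p)
}

#' Odds ratio of a 2x2 table
#'
#' Cross-product ratio `(a d)/(b c)` of `rbind(c(a, b), c(c, d))`. A zero
#' off-diagonal product gives `Inf` unless the Haldane-Anscombe correction
#' (+0.5 to every cell) is requested.
#'
#' @param table 2x2 numeric matrix of non-negative counts.
#' @param haldane Apply the +0.5 correction.
#' @return Odds ratio.
#' @export
odds_ratio <- function(table, haldane = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stopf("need a 2x2 table")
  if (any(table < 0)) stopf("negative cell count")
  if (haldane) table <- table + 0.5
  num <- table[1L, 1L] * table[2L, 2L]
  den <- table[1L, 2L] * table[2L, 1L]
  if (den == 0) return(Inf)
  num / den
}

#' Fisher exact test (two-sided)
#'
#' Exact two-sided p for a 2x2 table: the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed the observed one.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0))
    stopf("need a 2x2 table of non-negative counts")
  stats::fisher.test(table)$p.value
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; ties get mid-ranks (normal approximation
#' in that case, exact otherwise). Identical vectors return p = 1.
#'
#' @param x,y Paired numeric vectors.
#' @return Two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (all(x == y)) return(1)
  suppressWarnings(stats::wilcox.test(x, y, paired = TRUE)$p.value)
}

#' Wilcoxon rank-sum test for two independent samples
#'
#' @param x,y Numeric vectors.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  suppressWarnings(stats::wilcox.test(x, y)$p.value)
}

#' Independent two-sample t test on time lags
#'
#' Pooled-variance (equal variance) t test, as conventional for comparing
#' follower lags between groups.
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @return Two-sided p-value.
#' @export
lag_ttest <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stopf("each group needs at least 2 lags")
  if (stats::sd(c(x - mean(x), y - mean(y))) == 0) return(1)
  stats::t.test(x, y, var.equal = TRUE)$p.value
}

#' Region-level IED occurrence
#'
#' Percentage of sampled regions with at least one spike / one sharp
#' transient, per region label. A region unit is one (patient, side,
#' region) triple: multiple contacts within the same region of one patient
#' count once, and the left and right instances of a nucleus are distinct
#' sampled regions.
#'
#' @param records Data frame with columns `patient`, `side`, `region`,
#'   `spike` (logical), `st` (logical); one row per contact or per region
#'   (duplicates are merged with `any()`).
#' @return Data frame: `region`, `n_sampled`, `spike_pct`, `st_pct`
#'   (half-up integer percents) plus raw columns.
#' @export
region_occurrence <- function(records) {
  stopifnot(all(c("patient", "side", "region", "spike", "st") %in%
                  names(records)))
  records <- records[records$region %in% ALL_REGIONS, , drop = FALSE]
  key <- interaction(records$patient, records$side, records$region,
                     drop = TRUE)
  agg <- do.call(rbind, lapply(split(records, key), function(g)
    data.frame(region = g$region[1L], spike = any(g$spike), st = any(g$st))))
  out <- do.call(rbind, lapply(split(agg, agg$region), function(g)
    data.frame(region = g$region[1L], n_sampled = nrow(g),
               spike_raw = 100 * mean(g$spike),
               st_raw = 100 * mean(g$st))))
  out$spike_pct <- round_half_up(out$spike_raw)
  out$st_pct <- round_half_up(out$st_raw)
  rownames(out) <- NULL
  out[match(intersect(ALL_REGIONS, out$region), out$region), ]
}
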