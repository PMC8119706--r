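#' Region-wise hotspot/singleton enrichment versus the intronic/intergenic
#' baseline
#'
#' For each functional region the per-bp hotspot (or singleton) rate is
#' compared to the rate in the intronic/intergenic region, where limited
#' positive selection is expected. The fold change is the ratio of rates;
#' the one-sided p-value is the upper tail of the count under the baseline
#' rate applied to the region's length (exact binomial for lengths up to
#' 1e7 sites, Poisson beyond, where the two are numerically
#' indistinguishable). q-values are BH-adjusted across regions.
#'
#' @param counts Named integer vector: hotspot/singleton count per region
#'   (must include the baseline region).
#' @param lengths Named numeric vector: bp extent per region.
#' @param baseline Baseline region name (default `"intronic_intergenic"`).
#' @return `data.table(region, count, length, rate, fold_change, p_value,
#'   q_value)`; the baseline row has fold change 1 and p 1.
#' @export
region_enrichment <- function(counts, lengths,
                              baseline = "intronic_intergenic") {
  stopifnot(baseline %in% names(counts), baseline %in% names(lengths))
  regs <- names(counts)
  rate0 <- counts[[baseline]] / lengths[[baseline]]
  out <- data.table(region = regs,
                    count = as.integer(counts[regs]),
                    length = as.numeric(lengths[regs]))
  out[, rate := count / length]
  if (rate0 <= 0) {
    # zero baseline: fold change undefined, flagged through NAs
    out[, `:=`(fold_change = NA_real_, p_value = NA_real_,
               q_value = NA_real_)]
    return(out[])
  }
  out[, fold_change := rate / rate0]
  pv <- numeric(nrow(out))
  for (i in seq_len(nrow(out))) {
    if (out$region[i] == baseline) { pv[i] <- 1; next }
    k <- out$count[i]; len <- out$length[i]
    if (k == 0) { pv[i] <- 1; next }
    if (len <= 1e7) {
      pv[i] <- pbinom(k - 1, size = round(len), prob = rate0,
                      lower.tail = FALSE)
    } else {
      pv[i] <- ppois(k - 1, lambda = rate0 * len, lower.tail = FALSE)
    }
  }
  out[, p_value := pv]
  out[, q_value := bh_adjust(ifelse(region == baseline, NA, p_value))]
  out[]
}

#' Cancer-gene fold-change enrichment with Clopper-Pearson intervals
#'
#' Fold change of the cancer-gene proportion in a cumulative hotspot group
#' over a baseline proportion: either the overall proportion of Cancer Gene
#' Census genes among all genes (e.g. 699/20,805), or the cancer-gene
#' proportion among the region's singleton mutations. The exact
#' Clopper-Pearson 95% interval on `k/n` is divided by the baseline
#' proportion (treated as a constant) to move it onto the fold-change
#' scale; the p-value is a binomial test of `k` out of `n` against the
#' baseline proportion.
#'
#' @param k Number of group members associated with cancer genes.
#' @param n Group size.
#' @param baseline_prop Baseline cancer-gene proportion.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row `data.table(k, n, proportion, baseline, fold_change,
#'   ci_low, ci_high, p_value)` on the fold-change scale.
#' @export
cgc_fold_change <- function(k, n, baseline_prop, conf_level = 0.95) {
  if (n == 0) {
    return(data.table(k = 0L, n = 0L, proportion = NA_real_,
                      baseline = baseline_prop, fold_change = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_,
                      p_value = NA_real_))
  }
  bt <- binom.test(k, n, p = baseline_prop, conf.level = conf_level)
  prop <- k / n
  data.table(k = as.integer(k), n = as.integer(n), proportion = prop,
             baseline = baseline_prop,
             fold_change = prop / baseline_prop,
             ci_low = bt$conf.int[1] / baseline_prop,
             ci_high = bt$conf.int[2] / baseline_prop,
             p_value = bt$p.value)
}

#' Exact Clopper-Pearson interval on a proportion
#' @param k Successes; `n` trials; `conf_level` confidence level.
#' @param n,conf_level See above.
#' @return Numeric `c(low, high)` on the proportion scale.
#' @export
clopper_pearson <- function(k, n, conf_level = 0.95) {
  alpha <- 1 - conf_level
  low <- if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1)
  high <- if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k)
  c(low, high)
}

#' Second-hit missense test for gene regulatory hotspots
#'
#' Tests whether gene regulatory hotspots carry same-patient missense
#' mutations in the associated gene's coding region more often than gene
#' regulatory singletons do. Two-sided Fisher's exact test on the 2x2 table
#' (hotspots with/without a second hit vs singletons with/without); both
#' the conditional-MLE odds ratio and the plain ratio of proportions are
#' reported.
#'
#' @param hot_with,hot_without Hotspot counts with/without a second hit.
#' @param single_with,single_without Singleton counts with/without.
#' @return `data.table(odds_ratio, ratio_of_proportions, p_value)` (odds
#'   ratio `NA` on an empty margin, p 1).
#' @export
second_hit_test <- function(hot_with, hot_without, single_with,
                            single_without) {
  tab <- matrix(c(hot_with, hot_without, single_with, single_without),
                nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(data.table(odds_ratio = NA_real_,
                      ratio_of_proportions = NA_real_, p_value = 1))
  }
  ft <- fisher.test(tab)
  rp <- (hot_with / (hot_with + hot_without)) /
    (single_with / (single_with + single_without))
  data.table(odds_ratio = unname(ft$estimate),
             ratio_of_proportions = rp, p_value = ft$p.value)
}

#' Find hotspots/singletons with same-patient second-hit missense mutations
#'
#' A regulatory hotspot (or singleton) "has a second hit" iff at least one
#' of its patients carries a missense call in the same gene.
#'
#' @param members `data.table` with `patient, gene_id` for each regulatory
#'   hotspot member (plus `hotspot_id`) or singleton.
#' @param coding_missense `data.table(patient, gene_id)` of missense calls.
#' @param by Grouping column (`"hotspot_id"` for hotspots; for singletons
#'   each row is its own unit, pass `NULL`).
#' @return Logical vector per group (ordered by group) or per row.
#' @export
has_second_hit <- function(members, coding_missense, by = "hotspot_id") {
  key <- paste(coding_missense$patient, coding_missense$gene_id)
  hit <- paste(members$patient, members$gene_id) %in% key
  if (is.null(by)) return(hit)
  members <- as.data.table(members)
  members[, .(second_hit = any(hit[.I])), by = by][[2]]
}
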