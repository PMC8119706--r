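#' Per-hotspot delta-CAF p-value against matched singletons
#'
#' One-sided Wilcoxon rank-sum test comparing the hotspot members'
#' delta-CAF z-scores against the z-scores of singleton mutations in the
#' same functional region of the same gene (alternative: hotspot greater,
#' i.e. earlier/more clonal). Undefined without matched singletons or
#' without defined hotspot z-scores.
#'
#' @param hotspot_z Hotspot members' delta-CAF z-scores.
#' @param singleton_z Matched singletons' delta-CAF z-scores.
#' @return p-value or `NA`.
#' @export
hotspot_caf_pvalue <- function(hotspot_z, singleton_z) {
  hotspot_z <- hotspot_z[!is.na(hotspot_z)]
  singleton_z <- singleton_z[!is.na(singleton_z)]
  if (!length(hotspot_z) || !length(singleton_z)) return(NA_real_)
  wilcoxon_pvalue(hotspot_z, singleton_z, "greater")
}

#' Combine p-values with Fisher's method
#'
#' `X = -2 * sum(ln p_i)` is chi-squared with `2k` degrees of freedom under
#' the null. With a single defined p-value the combination equals it;
#' with none, `NA`. Zero p-values are floored at 1e-300 (flagged via the
#' `floored` attribute) so the rank score stays finite.
#'
#' @param p_values Numeric vector (NAs dropped).
#' @return Combined p-value.
#' @export
combine_fisher <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (!length(p)) return(NA_real_)
  floored <- any(p < 1e-300)
  p <- pmax(p, 1e-300)
  if (any(p > 1)) stop("p-values must be <= 1")
  out <- if (length(p) == 1) p else {
    pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
  }
  attr(out, "floored") <- floored
  out
}

#' Rank score from a combined p-value
#' @param combined_p Combined p-value.
#' @return `-log2(p)`; `NA` for missing p.
#' @export
rank_score <- function(combined_p) {
  -log2(pmax(combined_p, 1e-300))
}

#' Order the hotspot catalog by driver evidence
#'
#' Rows with a combined p-value are sorted by rank score (`-log2 p`)
#' descending; rows missing both component p-values follow, ordered by
#' multiplicity descending. Stable tie-break by chromosome and start
#' coordinate.
#'
#' @param rows Catalog `data.table` with `combined_p`, `multiplicity`,
#'   `chrom`, `start`.
#' @return The rows reordered, with a `rank` column added.
#' @export
rank_catalog <- function(rows) {
  rows <- as.data.table(rows)
  if (nrow(rows) == 0) {
    rows[, rank := integer()]
    return(rows[])
  }
  has_p <- !is.na(rows$combined_p)
  scored <- rows[has_p][order(-rank_score(combined_p), chrom, start)]
  unscored <- rows[!has_p][order(-multiplicity, chrom, start)]
  out <- rbindlist(list(scored, unscored))
  out[, rank := .I]
  out[]
}

#' Assemble and rank the per-hotspot driver-evidence catalog
#'
#' Joins the annotated hotspot table with per-hotspot delta-CAF and
#' expression p-values, combines them with Fisher's method (with the
#' single-p fallback), computes the rank score, and orders the catalog.
#' Combined p-values are deliberately not multiple-testing corrected; they
#' rank hotspots, they do not call significance.
#'
#' @param hotspots Annotated hotspot table.
#' @param caf_p,expr_p Numeric vectors aligned with `hotspots` rows (NA
#'   where undefined).
#' @param caf_median_z,expr_median_z Optional aligned medians for
#'   reporting.
#' @return Ranked catalog `data.table`.
#' @export
build_catalog <- function(hotspots, caf_p, expr_p,
                          caf_median_z = NA_real_,
                          expr_median_z = NA_real_) {
  rows <- copy(as.data.table(hotspots))
  rows[, `:=`(caf_p = caf_p, expr_p = expr_p,
              caf_median_z = caf_median_z,
              expr_median_z = expr_median_z)]
  rows[, combined_p := vapply(seq_len(.N), function(i) {
    as.numeric(combine_fisher(c(caf_p[i], expr_p[i])))
  }, numeric(1))]
  rows[, rank_score := ifelse(is.na(combined_p), NA_real_,
                              rank_score(combined_p))]
  rank_catalog(rows)
}
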