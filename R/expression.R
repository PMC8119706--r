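#' Per-cohort expression z-scores
#'
#' Normalizes raw expression values within each (gene, cohort) cell:
#' `z = (value - mean(cohort)) / sd(cohort)` with the sample standard
#' deviation, so values are comparable across cancer types. Cells with
#' fewer than two measured patients, or zero spread, give `NA`.
#'
#' @param matrix Numeric genes x patients matrix.
#' @param cohort_labels Named character vector mapping patient -> cohort
#'   (or a vector aligned with `colnames(matrix)`).
#' @return Matrix of z-scores, same shape and dimnames.
#' @export
expression_zscores <- function(matrix, cohort_labels) {
  if (!is.null(names(cohort_labels))) {
    cohort_labels <- cohort_labels[colnames(matrix)]
  }
  z <- matrix * NA_real_
  for (coh in unique(cohort_labels)) {
    ci <- which(cohort_labels == coh)
    if (length(ci) < 2) next
    sub <- matrix[, ci, drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE)
    sdv <- apply(sub, 1, sd, na.rm = TRUE)
    sdv[sdv == 0] <- NA
    z[, ci] <- (sub - mu) / sdv
  }
  z
}

#' Wild-type patient set for a gene
#'
#' Patients qualify as wild-type for a gene if they have no copy-number
#' change (every overlapping segment has copy number exactly 2; patients
#' with no segment over the gene are assumed diploid) and carry no SNV or
#' indel in the gene's protein-coding region or regulatory regions
#' (splice-sites, promoters, and UTRs). Enhancer mutations do not
#' disqualify by default — distal elements are kept out of the exclusion
#' list — set `exclude_enhancers = TRUE` to tighten.
#'
#' @param gene Gene id.
#' @param mutations A `mutation_table`.
#' @param regions Region table (`chrom, start, end, region_class, gene_id`).
#' @param cn_segments `data.table(patient, chrom, start, end, copy_number)`.
#' @param patients Character vector of all candidate patients.
#' @param exclude_enhancers Also exclude patients with enhancer mutations
#'   in the gene (default FALSE).
#' @return Character vector of wild-type patient ids.
#' @export
wildtype_set <- function(gene, mutations, regions, cn_segments, patients,
                         exclude_enhancers = FALSE) {
  regions <- as.data.table(regions)
  excl_classes <- c("protein_coding", "protein_splice_site",
                    "noncoding_splice_site", "UTR5", "UTR3", "promoter")
  if (exclude_enhancers) excl_classes <- c(excl_classes, "enhancer")
  gr <- regions[gene_id == gene & region_class %in% excl_classes]
  bad <- character(0)
  if (nrow(gr) && nrow(mutations)) {
    muts <- as.data.table(mutations)
    for (chr in unique(gr$chrom)) {
      mi <- which(muts$chrom == chr)
      if (!length(mi)) next
      rr <- gr[chrom == chr]
      qs <- muts$start[mi]; qe <- pmax(muts$end[mi], muts$start[mi] + 1L)
      q <- IRanges::IRanges(start = qs + 1L, end = qe)
      s <- IRanges::IRanges(start = rr$start + 1L, end = rr$end)
      bad <- union(bad, muts$patient[mi[IRanges::overlapsAny(q, s)]])
    }
  }
  # CN != 2 over the gene body (protein_coding span; fall back to any
  # interval of the gene)
  body <- regions[gene_id == gene & region_class == "protein_coding"]
  if (nrow(body) == 0) body <- regions[gene_id == gene]
  if (nrow(body) && nrow(cn_segments)) {
    seg <- as.data.table(cn_segments)[copy_number != 2]
    for (i in seq_len(nrow(body))) {
      hit <- seg[chrom == body$chrom[i] & start < body$end[i] &
                   end > body$start[i]]
      bad <- union(bad, hit$patient)
    }
  }
  setdiff(patients, bad)
}

#' Class-dependent alternative hypothesis for expression tests
#'
#' One-sided "greater" for oncogenes (activation expected to raise
#' expression), one-sided "less" for tumor suppressors (nonsense-mediated
#' decay and inactivation), two-sided otherwise.
#'
#' @param cgc_class One of `oncogene`, `tsg`, `other_cgc`, `non_cancer`.
#' @return `"greater"`, `"less"`, or `"two.sided"`.
#' @export
expression_alternative <- function(cgc_class) {
  switch(cgc_class,
         oncogene = "greater",
         tsg = "less",
         "two.sided")
}

#' Wilcoxon rank-sum test of a hotspot group's expression against wild-type
#'
#' @param group_z Expression z-scores for mutated patients.
#' @param wildtype_z Expression z-scores for the wild-type set.
#' @param cgc_class Gene class; sets the alternative via
#'   [expression_alternative()].
#' @return `data.table(shift, p_value, n_group, n_wildtype)` where `shift`
#'   is the difference of medians (group minus wild-type); `NA` p-value
#'   when either side is empty.
#' @export
group_expression_test <- function(group_z, wildtype_z, cgc_class) {
  group_z <- group_z[!is.na(group_z)]
  wildtype_z <- wildtype_z[!is.na(wildtype_z)]
  if (!length(group_z) || !length(wildtype_z)) {
    return(data.table(shift = NA_real_, p_value = NA_real_,
                      n_group = length(group_z),
                      n_wildtype = length(wildtype_z)))
  }
  alt <- expression_alternative(cgc_class)
  p <- wilcoxon_pvalue(group_z, wildtype_z, alt)
  data.table(shift = median(group_z) - median(wildtype_z), p_value = p,
             n_group = length(group_z), n_wildtype = length(wildtype_z))
}

# Exact Wilcoxon for small untied samples, normal approximation with
# continuity correction otherwise (wilcox.test chooses; we force exact
# under m + n <= 50 without ties).
wilcoxon_pvalue <- function(x, y, alternative) {
  exact <- (length(x) + length(y) <= 50) && !anyDuplicated(c(x, y))
  p <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE)$p.value)
  if (is.nan(p)) p <- 1  # fully tied samples carry no evidence
  p
}

#' Per-hotspot expression p-value against the gene's wild-type set
#'
#' @param hotspot_z z-scores of the hotspot's mutated patients (with
#'   expression data).
#' @param wildtype_z Wild-type z-scores for the same gene.
#' @param cgc_class Gene class (sets sidedness).
#' @return p-value, or `NA` when either side is empty.
#' @export
hotspot_expression_pvalue <- function(hotspot_z, wildtype_z, cgc_class) {
  hotspot_z <- hotspot_z[!is.na(hotspot_z)]
  wildtype_z <- wildtype_z[!is.na(wildtype_z)]
  if (!length(hotspot_z) || !length(wildtype_z)) return(NA_real_)
  wilcoxon_pvalue(hotspot_z, wildtype_z, expression_alternative(cgc_class))
}
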