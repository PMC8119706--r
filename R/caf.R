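#' Cancer allele fraction (purity/copy-number-corrected VAF)
#'
#' `CAF = VAF * (CN * TP + 2 * (1 - TP)) / (CN * TP)` where `CN` is the
#' copy number at the position and `TP` the sample's tumor purity. Values
#' may exceed 1 (multi-copy variants) and are not clipped; `CN * TP == 0`
#' yields `NA`.
#'
#' @param vaf Variant allele fraction in `[0, 1]`.
#' @param cn Copy number at the position.
#' @param tp Tumor purity in `(0, 1]`.
#' @return CAF (vectorized).
#' @export
compute_caf <- function(vaf, cn, tp) {
  n <- max(length(vaf), length(cn), length(tp))
  vaf <- rep_len(vaf, n); cn <- rep_len(cn, n); tp <- rep_len(tp, n)
  denom <- cn * tp
  out <- vaf * (denom + 2 * (1 - tp)) / denom
  out[!is.finite(denom) | denom <= 0] <- NA_real_
  out
}

#' Copy number at positions from per-patient segments
#'
#' Positions falling in a gap between segments get the diploid default
#' `CN = 2` and are flagged.
#'
#' @param mutations `data.table(patient, chrom, start)`.
#' @param cn_segments `data.table(patient, chrom, start, end, copy_number)`
#'   (0-based half-open, non-overlapping per patient/chromosome).
#' @return `data.table(copy_number, cn_gap)` aligned to `mutations` rows.
#' @export
copy_number_at <- function(mutations, cn_segments) {
  mutations <- as.data.table(mutations)
  cn_segments <- as.data.table(cn_segments)
  out <- data.table(copy_number = rep(2, nrow(mutations)),
                    cn_gap = rep(TRUE, nrow(mutations)))
  if (nrow(cn_segments) == 0 || nrow(mutations) == 0) return(out[])
  m <- copy(mutations)[, row0 := .I]
  m[, pos := start]
  seg <- copy(cn_segments)
  setkey(seg, patient, chrom, start, end)
  q <- m[, .(patient, chrom, start = pos, end = pos + 1L, row0)]
  setkey(q, patient, chrom, start, end)
  ov <- foverlaps(q, seg, type = "within", nomatch = NULL)
  if (nrow(ov)) {
    out$copy_number[ov$row0] <- ov$copy_number
    out$cn_gap[ov$row0] <- FALSE
  }
  out[]
}

#' Delta-CAF against the nearest eligible same-patient mutation
#'
#' For each mutation, the reference point is the nearest same-patient,
#' same-chromosome mutation at least `min_dist` bp away whose position lies
#' outside protein-coding gene bodies (that restriction keeps the reference
#' neutral to coding selection, and the distance requirement keeps it
#' outside the same local copy-number event). `delta_caf = caf - caf(ref)`,
#' undefined when no eligible neighbor exists.
#'
#' @param mutations `data.table` with `patient, chrom, start, caf`.
#' @param coding_intervals `data.table(chrom, start, end)` protein-coding
#'   gene body spans (0-based half-open); mutations inside are ineligible
#'   as reference points.
#' @param min_dist Minimum separation in bp (default 2000).
#' @return Numeric vector `delta_caf` aligned to `mutations` rows.
#' @export
compute_delta_caf <- function(mutations, coding_intervals = NULL,
                              min_dist = 2000L) {
  mutations <- as.data.table(mutations)
  n <- nrow(mutations)
  if (n == 0) return(numeric(0))
  eligible <- rep(TRUE, n)
  if (!is.null(coding_intervals) && nrow(coding_intervals)) {
    ci <- as.data.table(coding_intervals)
    for (chr in unique(mutations$chrom)) {
      mi <- which(mutations$chrom == chr)
      rr <- ci[chrom == chr]
      if (nrow(rr) == 0) next
      q <- IRanges::IRanges(start = mutations$start[mi] + 1L,
                            width = 1L)
      s <- IRanges::IRanges(start = rr$start + 1L, end = rr$end)
      eligible[mi[IRanges::overlapsAny(q, s)]] <- FALSE
    }
  }
  eligible <- eligible & !is.na(mutations$caf)
  delta <- rep(NA_real_, n)
  idx <- split(seq_len(n), list(mutations$patient, mutations$chrom),
               drop = TRUE)
  for (ii in idx) {
    el <- ii[eligible[ii]]
    if (!length(el)) next
    epos <- mutations$start[el]
    o <- order(epos); el <- el[o]; epos <- epos[o]
    ecaf <- mutations$caf[el]
    p <- mutations$start[ii]
    # rightmost eligible position <= p - min_dist
    li <- findInterval(p - min_dist, epos)
    # leftmost eligible position >= p + min_dist (positions are integers)
    ri <- findInterval(p + min_dist - 1L, epos) + 1L
    dl <- ifelse(li >= 1L, p - epos[pmax(li, 1L)], Inf)
    dr <- ifelse(ri <= length(epos), epos[pmin(ri, length(epos))] - p, Inf)
    j <- ifelse(dl <= dr, li, ri)
    have <- is.finite(pmin(dl, dr)) & !is.na(mutations$caf[ii])
    delta[ii[have]] <- mutations$caf[ii[have]] - ecaf[j[have]]
  }
  delta
}

#' z-score normalization with sample standard deviation
#'
#' `(x - mean(x)) / sd(x)` over the defined values (n-1 denominator);
#' missing values stay missing. Zero spread yields all-`NA` with a warning.
#'
#' @param values Numeric vector.
#' @return z-scores, same length.
#' @export
zscore_normalize <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) return(rep(NA_real_, length(values)))
  s <- sd(values[ok])
  if (!is.finite(s) || s == 0) {
    warning("zero spread; z-scores undefined")
    return(rep(NA_real_, length(values)))
  }
  (values - mean(values[ok])) / s
}

#' Permutation test of group median delta-CAF z-scores
#'
#' Shuffles group labels jointly over all values in each of `n_perm`
#' permutations and collects per-group null medians. Singleton-labeled
#' groups are downsampled once (fraction `singleton_downsample`) before
#' permuting. The primary p-value per group is the proportion of null
#' medians at or above the observed median; an add-one version
#' `(1 + #{null >= obs}) / (1 + n_perm)` avoids zero p-values. q-values
#' are BH-adjusted across groups.
#'
#' @param z Numeric vector of z-scores.
#' @param group Group label per value.
#' @param singleton_groups Labels treated as singleton groups for
#'   downsampling (default those containing `"singleton"`).
#' @param n_perm Number of permutations (default 100000).
#' @param singleton_downsample Retained fraction of singleton values
#'   (default 0.10).
#' @param seed Integer seed.
#' @return `data.table(group, n, median, p_value, p_value_addone, q_value)`.
#' @export
group_median_permutation_test <- function(z, group,
                                          singleton_groups = NULL,
                                          n_perm = 100000L,
                                          singleton_downsample = 0.10,
                                          seed = 1L) {
  ok <- !is.na(z) & !is.na(group)
  z <- z[ok]; group <- as.character(group[ok])
  if (is.null(singleton_groups)) {
    singleton_groups <- grep("singleton", unique(group), value = TRUE)
  }
  set.seed(seed)
  keep <- rep(TRUE, length(z))
  for (g in singleton_groups) {
    gi <- which(group == g)
    if (length(gi)) {
      keep[gi] <- FALSE
      keep[sample(gi, max(1L, round(length(gi) * singleton_downsample)))] <- TRUE
    }
  }
  z <- z[keep]; group <- group[keep]
  groups <- unique(group)
  sizes <- table(group)[groups]
  obs <- vapply(groups, function(g) median(z[group == g]), numeric(1))
  counts <- setNames(numeric(length(groups)), groups)
  gidx <- split(seq_along(z), group)[groups]
  for (it in seq_len(n_perm)) {
    perm <- sample(z)
    for (j in seq_along(groups)) {
      if (median(perm[gidx[[j]]]) >= obs[j]) counts[j] <- counts[j] + 1
    }
  }
  data.table(group = groups, n = as.integer(sizes), median = obs,
             p_value = counts / n_perm,
             p_value_addone = (1 + counts) / (1 + n_perm),
             q_value = bh_adjust(counts / n_perm))
}

#' High / above-median delta-CAF flags relative to a reference group
#'
#' `high` means strictly above the reference group's 90th percentile;
#' `above_median` strictly above its median. The thresholds are computed
#' from the supplied reference distribution (typically
#' protein-coding hotspots in cancer genes).
#'
#' @param z z-scores to flag.
#' @param reference_z Reference group's z-scores.
#' @return `data.table(high, above_median)` plus attributes
#'   `threshold_high`, `threshold_median`.
#' @export
flag_caf_levels <- function(z, reference_z) {
  reference_z <- reference_z[!is.na(reference_z)]
  if (!length(reference_z)) stop("empty reference group")
  th_hi <- quantile(reference_z, 0.9, names = FALSE)
  th_med <- median(reference_z)
  out <- data.table(high = z > th_hi, above_median = z > th_med)
  setattr(out, "threshold_high", th_hi)
  setattr(out, "threshold_median", th_med)
  out[]
}
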