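#' Detect SNV hotspots
#'
#' A site-specific SNV hotspot is a genomic position where two or more
#' distinct patients carry an SNV; the nucleotide change is allowed to vary
#' between patients. A patient contributes at most 1 to the multiplicity,
#' however many calls they have at the position; extra same-patient calls
#' remain members.
#'
#' @param table A filtered `mutation_table`.
#' @param min_recurrence Minimum number of distinct patients (default 2).
#' @return List with `hotspots` (data.table: `hotspot_id, chrom, start, end,
#'   mut_type, multiplicity, n_calls, alts`) and `members` (the contributing
#'   mutation rows with a `hotspot_id` column).
#' @export
detect_snv_hotspots <- function(table, min_recurrence = 2L) {
  detect_point_hotspots(table, "SNV", min_recurrence)
}

#' Detect insertion hotspots
#'
#' An insertion hotspot is an inter-base boundary where two or more distinct
#' patients carry an insertion; insert sequence and length may vary.
#'
#' @inheritParams detect_snv_hotspots
#' @return As [detect_snv_hotspots()].
#' @export
detect_insertion_hotspots <- function(table, min_recurrence = 2L) {
  detect_point_hotspots(table, "INS", min_recurrence)
}

detect_point_hotspots <- function(table, type, min_recurrence = 2L) {
  muts <- as.data.table(table)[mut_type == type]
  if (nrow(muts) == 0) return(empty_hotspot_result(type))
  muts <- muts[order(chrom, start, patient)]
  # cheap pre-filter: only sites with >= min_recurrence calls can qualify
  cnt <- muts[, .N, by = .(chrom, start)][N >= min_recurrence]
  cand <- muts[cnt[, .(chrom, start)], on = c("chrom", "start")]
  if (nrow(cand) == 0) return(empty_hotspot_result(type))
  cand[, hotspot_id := paste0(tolower(type), "_", chrom, "_", start)]
  hs <- cand[, .(chrom = chrom[1], start = start[1], end = end[1],
                 mut_type = type,
                 multiplicity = uniqueN(patient), n_calls = .N,
                 alts = paste(sort(unique(alt)), collapse = ",")),
             by = hotspot_id]
  hs <- hs[multiplicity >= min_recurrence]
  members <- cand[hotspot_id %in% hs$hotspot_id]
  list(hotspots = hs[order(chrom, start)], members = members[])
}

empty_hotspot_result <- function(type) {
  list(hotspots = data.table(hotspot_id = character(), chrom = character(),
                             start = integer(), end = integer(),
                             mut_type = character(), multiplicity = integer(),
                             n_calls = integer(), alts = character()),
       members = data.table())
}

#' Detect deletion hotspots
#'
#' Deletions contribute to the same hotspot if they overlap fully or
#' partially, or if the deleted nucleotides are right next to each other
#' (abutting; a 1 bp gap separates). Clusters are the connected components
#' of that overlap-or-adjacent relation (single-linkage; computed with
#' `IRanges::reduce`). Clusters containing deletions from at least
#' `min_recurrence` distinct patients become hotspots whose span is the
#' union extent of their members.
#'
#' @inheritParams detect_snv_hotspots
#' @return As [detect_snv_hotspots()].
#' @export
detect_deletion_hotspots <- function(table, min_recurrence = 2L) {
  muts <- as.data.table(table)[mut_type == "DEL"]
  if (nrow(muts) == 0) return(empty_hotspot_result("DEL"))
  muts <- muts[order(chrom, start, end, patient)]
  # single-linkage sweep: sorted by start, a new cluster opens when the
  # next deletion starts strictly beyond the running span end (gap >= 1 bp
  # separates; abutting spans merge)
  muts[, hotspot_id := {
    run_end <- cummax(end)
    new_cluster <- c(TRUE, start[-1] > run_end[-.N])
    cl <- cumsum(new_cluster)
    cs <- tapply(start, cl, min)[cl]
    ce <- tapply(end, cl, max)[cl]
    paste0("del_", chrom, "_", cs, "_", ce)
  }, by = chrom]
  hs <- muts[, .(chrom = chrom[1], start = min(start), end = max(end),
                 mut_type = "DEL",
                 multiplicity = uniqueN(patient), n_calls = .N,
                 alts = ""),
             by = hotspot_id]
  hs <- hs[multiplicity >= min_recurrence]
  members <- muts[hotspot_id %in% hs$hotspot_id]
  list(hotspots = hs[order(chrom, start)], members = members[])
}

#' Remove duplicated same-patient indel calls
#'
#' Different callers occasionally emit the same indel twice for a patient
#' with minor representation differences (a start/end shift, a differing
#' insert, or disagreeing read counts). After left-normalization, two
#' same-patient calls of the same indel type whose start and end each differ
#' by at most `shift_tol` are judged duplicates, and *both* copies are
#' removed. Recurrence across different patients is never touched.
#'
#' @param table A `mutation_table` (indels left-normalized).
#' @param shift_tol Maximum coordinate shift (default 1).
#' @return Filtered table; attribute `n_removed` counts removed calls.
#' @export
dedupe_indels <- function(table, shift_tol = 1L) {
  dt <- copy(as.data.table(table))
  dt[, is_dup := FALSE]
  idx <- which(dt$mut_type %in% c("INS", "DEL"))
  if (length(idx)) {
    sub <- dt[idx][, row0 := idx]
    setorder(sub, patient, chrom, mut_type, start, end)
    grp <- sub[, .(rows = list(row0), starts = list(start), ends = list(end)),
               by = .(patient, chrom, mut_type)]
    for (g in seq_len(nrow(grp))) {
      rows <- grp$rows[[g]]; ss <- grp$starts[[g]]; ee <- grp$ends[[g]]
      n <- length(rows)
      if (n < 2L) next
      for (a in seq_len(n - 1L)) {
        for (b in (a + 1L):n) {
          if (ss[b] - ss[a] > shift_tol) break
          if (abs(ss[b] - ss[a]) <= shift_tol && abs(ee[b] - ee[a]) <= shift_tol) {
            dt$is_dup[rows[a]] <- TRUE
            dt$is_dup[rows[b]] <- TRUE
          }
        }
      }
    }
  }
  n_removed <- sum(dt$is_dup)
  out <- dt[is_dup == FALSE][, is_dup := NULL]
  setattr(out, "class", class(table))
  setattr(out, "n_removed", n_removed)
  out[]
}

#' Locate maximal homopolymer runs in a reference sequence
#'
#' @param reference Named list/character of chromosome sequences or a
#'   `DNAStringSet`.
#' @param min_run Minimum run length in bp (default 9).
#' @return `data.table(chrom, start, end, base)` with 0-based half-open
#'   coordinates of each maximal run of identical bases of length
#'   `>= min_run`.
#' @export
homopolymer_runs <- function(reference, min_run = 9L) {
  reference <- as_reference_list(reference)
  homopolymer_runs_vec(lapply(reference, function(s) strsplit(s, "")[[1]]),
                       min_run)
}

# same, on per-base character vectors (avoids splitting large strings)
homopolymer_runs_vec <- function(ref_vec, min_run = 9L) {
  out <- vector("list", length(ref_vec))
  for (i in seq_along(ref_vec)) {
    chr <- names(ref_vec)[i]
    r <- rle(ref_vec[[i]])
    ends <- cumsum(r$lengths)
    keep <- which(r$lengths >= min_run)
    if (!length(keep)) next
    out[[i]] <- data.table(chrom = chr,
                           start = ends[keep] - r$lengths[keep],
                           end = ends[keep],
                           base = r$values[keep])
  }
  out <- rbindlist(out[!vapply(out, is.null, logical(1))])
  if (nrow(out) == 0) {
    out <- data.table(chrom = character(), start = integer(),
                      end = integer(), base = character())
  }
  out[]
}

#' Flag variants or hotspots on the border of a homopolymer run
#'
#' A variant borders a homopolymer run if its span, or either immediately
#' flanking base, overlaps a maximal run of at least `min_run` identical
#' reference bases. Indel hotspots flagged this way are slippage-artifact
#' candidates and are removed downstream; SNV hotspots are only annotated.
#'
#' @param spans `data.table(chrom, start, end)` (0-based half-open; for
#'   insertions `start == end`).
#' @param runs Output of [homopolymer_runs()], or a reference to compute it
#'   from.
#' @param min_run Used only when `runs` is a reference sequence.
#' @return Logical vector, one flag per span row.
#' @export
homopolymer_flag <- function(spans, runs, min_run = 9L) {
  spans <- as.data.table(spans)
  if (!is.data.frame(runs)) runs <- homopolymer_runs(runs, min_run)
  if (nrow(spans) == 0) return(logical(0))
  flags <- logical(nrow(spans))
  if (nrow(runs) == 0) return(flags)
  for (chr in unique(spans$chrom)) {
    si <- which(spans$chrom == chr)
    rr <- runs[chrom == chr]
    if (nrow(rr) == 0) next
    # widen by 1 bp on each side: "span or either flanking base"
    q <- IRanges::IRanges(start = spans$start[si] - 1L + 1L,
                          end = spans$end[si] + 1L)
    s <- IRanges::IRanges(start = rr$start + 1L, end = rr$end)
    flags[si] <- IRanges::overlapsAny(q, s)
  }
  flags
}

#' Site-specific noise score (per non-reference nucleotide)
#'
#' For a position and a non-reference nucleotide `a`, the noise score is
#' `sum over cohorts c of log10(p(a, c) + 1)` where `p(a, c)` is the percent
#' (0-100) of normal samples in cohort `c` with at least two reads supporting
#' `a`. With several observed alternate alleles the maximum score over the
#' observed alleles is taken (conservative).
#'
#' @param profile `data.table(chrom, pos_1based, alt, cohort, percent)` noise
#'   profile rows covering the position.
#' @param alts Character vector of observed non-reference nucleotides.
#' @return Single numeric score, or `NA` if no profile rows cover any
#'   observed allele.
#' @export
noise_score <- function(profile, alts) {
  profile <- as.data.table(profile)
  sub <- profile[alt %in% alts]
  if (nrow(sub) == 0) return(NA_real_)
  per_alt <- sub[, .(score = sum(log10(percent + 1))), by = alt]
  max(per_alt$score)
}

#' Apply the site-specific noise filter to the top SNV hotspots
#'
#' Scores the `top_k` SNV hotspots with the most patients (ties at the
#' boundary all included) using [noise_score()] and removes those scoring
#' strictly above `threshold`. Hotspots without profile coverage are
#' retained and flagged unscored.
#'
#' @param hotspots SNV hotspot table (needs `chrom, start, multiplicity,
#'   alts`).
#' @param profile Noise-profile `data.table(chrom, pos_1based, alt, cohort,
#'   percent)`.
#' @param top_k Number of highest-multiplicity hotspots to score
#'   (default 1000).
#' @param threshold Removal threshold on the score (default 20).
#' @return List: `hotspots` (kept, with `noise_score` column), `removed`
#'   (rows filtered out), `scored` (logical count info as attributes).
#' @export
apply_noise_filter <- function(hotspots, profile, top_k = 1000L,
                               threshold = 20) {
  hs <- copy(as.data.table(hotspots))
  hs[, noise_score := NA_real_]
  if (nrow(hs) == 0 || is.null(profile) || nrow(profile) == 0) {
    return(list(hotspots = hs[], removed = hs[0]))
  }
  profile <- as.data.table(profile)
  ord <- order(-hs$multiplicity)
  if (length(ord) > top_k) {
    cutoff <- hs$multiplicity[ord[top_k]]
    in_scope <- hs$multiplicity >= cutoff  # ties at rank top_k all included
  } else {
    in_scope <- rep(TRUE, nrow(hs))
  }
  prof_split <- split(profile, paste(profile$chrom, profile$pos_1based))
  for (i in which(in_scope)) {
    rows <- prof_split[[paste(hs$chrom[i], hs$start[i] + 1L)]]
    if (is.null(rows) || nrow(rows) == 0) next
    hs$noise_score[i] <- noise_score(rows, strsplit(hs$alts[i], ",")[[1]])
  }
  drop <- !is.na(hs$noise_score) & hs$noise_score > threshold
  list(hotspots = hs[!drop][], removed = hs[drop][])
}
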