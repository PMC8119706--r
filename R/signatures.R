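#' Default mutational-signature groupings
#'
#' Groups of COMPOSITE signature ids sharing a proposed etiology, used to
#' summarize per-hotspot signature attributions: APOBEC, mismatch repair,
#' UV, POLE, treatment, signature 17, prostate-specific, indel-driven, and
#' unknown-etiology signatures. Ungrouped ids pass through unchanged.
#'
#' @return Named list mapping group label -> character vector of signature
#'   ids.
#' @export
signature_groups <- function() {
  list(
    APOBEC = c("2", "13", "69"),
    MMR = c("6", "14", "15", "21", "26", "44", "73", "76", "79"),
    UV = c("7a", "7b", "7c", "38", "55", "65", "67"),
    POLE = c("9", "10a", "61", "62", "63", "66", "78"),
    Treatment = c("11", "22", "35"),
    Signature17 = c("17a", "17b"),
    Prostate = c("37", "80"),
    IndelDriven = c("64", "71", "77", "81", "82"),
    Unknown = c("8", "12", "19", "28", "30", "33", "39", "68", "70", "83")
  )
}

#' Per-hotspot mutational-signature profile
#'
#' Attributes signature probabilities to a hotspot by averaging the
#' per-mutation profiles of its members (unweighted over member mutations,
#' so each patient's own alt-specific attribution enters; differing
#' alternate alleles contribute their own vectors). The mean is
#' renormalized to sum 1. Members without a profile are skipped and
#' reported through the coverage fraction.
#'
#' @param members Hotspot member table (`patient, chrom, start, alt`).
#' @param profiles Per-mutation profile table
#'   `data.table(patient, chrom, pos_1based, alt, signature_id,
#'   probability)`.
#' @param per_patient Average per patient instead of per mutation
#'   (default FALSE).
#' @return List with `profile` (named numeric, sums to 1; NULL when no
#'   member has a profile) and `coverage` (fraction of members with a
#'   profile).
#' @export
hotspot_signature_profile <- function(members, profiles,
                                      per_patient = FALSE) {
  members <- as.data.table(members)
  profiles <- as.data.table(profiles)
  if (nrow(members) == 0) return(list(profile = NULL, coverage = 0))
  key_m <- paste(members$patient, members$chrom, members$start + 1L,
                 members$alt)
  key_p <- paste(profiles$patient, profiles$chrom, profiles$pos_1based,
                 profiles$alt)
  sel <- key_p %in% key_m
  sub <- profiles[sel]
  sub[, key := key_p[sel]]
  covered <- key_m %in% sub$key
  if (!any(covered)) return(list(profile = NULL, coverage = 0))
  # normalize each mutation's own profile, then average
  sub[, probability := probability / sum(probability), by = key]
  if (per_patient) {
    per <- sub[, .(probability = sum(probability) / uniqueN(key)),
               by = .(patient, signature_id)]
    agg <- per[, .(mass = sum(probability) / uniqueN(per$patient)),
               by = signature_id]
  } else {
    n_mut <- uniqueN(sub$key)
    agg <- sub[, .(mass = sum(probability) / n_mut), by = signature_id]
  }
  prof <- setNames(agg$mass, agg$signature_id)
  prof <- prof / sum(prof)
  list(profile = prof, coverage = mean(covered))
}

#' Aggregate a signature profile into etiology groups
#'
#' Group mass is the sum of member masses; total mass is conserved. Ids
#' absent from the grouping pass through under their own label. An id
#' appearing in two groups is an error.
#'
#' @param profile Named numeric vector of signature masses.
#' @param grouping Named list label -> ids (default [signature_groups()]).
#' @return Named numeric vector of grouped masses.
#' @export
group_signatures <- function(profile, grouping = signature_groups()) {
  if (is.null(profile) || !length(profile)) return(profile)
  all_ids <- unlist(grouping, use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    stop("signature id assigned to more than one group")
  }
  lut <- setNames(rep(names(grouping), lengths(grouping)), all_ids)
  labels <- ifelse(names(profile) %in% names(lut),
                   lut[names(profile)], names(profile))
  tapply_sum <- tapply(profile, labels, sum)
  out <- as.numeric(tapply_sum)
  names(out) <- names(tapply_sum)
  out
}

#' Top-k grouped signatures of a profile
#'
#' @param profile Named numeric vector (grouped or raw).
#' @param k How many (default 2). Ties broken by label.
#' @return Named numeric vector of the k largest masses.
#' @export
top_signatures <- function(profile, k = 2L) {
  if (is.null(profile) || !length(profile)) return(profile)
  ord <- order(-profile, names(profile))
  head(profile[ord], k)
}
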