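#' Expected number of sites with a given mutation multiplicity (uniform
#' binomial model)
#'
#' Assumes every patient scatters their mutations uniformly over the
#' genome, so each site is mutated in a given patient with probability
#' `p = M / (N * L)` and the number of mutated patients at a site is
#' `Binomial(N, p)`. The expected count of sites with at least (or exactly)
#' `k` mutated patients is `L * P(X >= k)` (`L * P(X = k)`), evaluated in
#' log space so that tiny tails at genome scale stay accurate.
#'
#' @param genome_length Number of sites `L`.
#' @param n_patients Number of patients `N`.
#' @param total_mutations Total mutation count `M` across all patients.
#' @param k Multiplicity (vectorized).
#' @param mode `"ge"` for at-least-k, `"eq"` for exactly-k.
#' @return Expected number of sites (numeric, same length as `k`).
#' @export
binomial_expected_counts <- function(genome_length, n_patients,
                                     total_mutations, k,
                                     mode = c("ge", "eq")) {
  mode <- match.arg(mode)
  stopifnot(genome_length > 0, n_patients > 0, total_mutations > 0)
  p <- total_mutations / (n_patients * genome_length)
  if (p >= 1) stop("per-site per-patient probability >= 1; model invalid")
  if (any(k < 0 | k > n_patients)) stop("k out of range 0..N")
  if (mode == "ge") {
    logtail <- ifelse(k == 0, 0,
                      pbinom(k - 1, n_patients, p, lower.tail = FALSE,
                             log.p = TRUE))
    exp(log(genome_length) + logtail)
  } else {
    exp(log(genome_length) + dbinom(k, n_patients, p, log = TRUE))
  }
}

#' One-sided upper-tail binomial p-value for a site's multiplicity
#'
#' `P(X >= k_observed)` with `X ~ Binomial(N, p)`.
#'
#' @param n_patients N.
#' @param p Per-patient mutation probability at the site.
#' @param k_observed Observed number of mutated patients (vectorized).
#' @return p-value(s) in `[0, 1]`.
#' @export
binomial_site_pvalue <- function(n_patients, p, k_observed) {
  if (any(k_observed > n_patients)) stop("k_observed > N")
  ifelse(k_observed <= 0, 1,
         pbinom(k_observed - 1, n_patients, p, lower.tail = FALSE))
}

#' Exact Poisson-binomial upper-tail p-value by convolution
#'
#' The number of mutated patients at a site under heterogeneous per-patient
#' probabilities follows a Poisson-binomial distribution. The full count
#' distribution is built by iterative convolution (exact, no approximation),
#' then the upper tail `P(X >= k)` is summed. Stable for a few thousand
#' patients.
#'
#' @param probs Numeric vector of per-patient probabilities in `[0, 1]`.
#' @param k_observed Observed multiplicity.
#' @return Exact `P(X >= k_observed)`.
#' @export
poisson_binomial_site_pvalue <- function(probs, k_observed) {
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  dp <- poisson_binomial_pmf(probs)
  if (k_observed <= 0) return(1)
  if (k_observed > length(probs)) stop("k_observed > number of patients")
  # sum the smaller tail for accuracy
  upper <- sum(dp[(k_observed + 1L):length(dp)])
  min(1, max(0, upper))
}

#' Full Poisson-binomial probability mass function
#' @param probs Per-trial success probabilities.
#' @return Numeric vector `P(X = 0), ..., P(X = n)`.
#' @export
poisson_binomial_pmf <- function(probs) {
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  dp <- 1
  for (p in probs) {
    dp <- c(dp * (1 - p), 0) + c(0, dp * p)
  }
  dp
}

#' Expected site counts under a per-site Poisson-binomial model
#'
#' Sums, over the supplied sites, the probability that the site reaches
#' multiplicity at least `k`, giving the model's expected number of
#' hotspots with `>= k` mutated patients.
#'
#' @param prob_matrix Numeric matrix, sites x patients, entries in `[0,1]`.
#' @param k Multiplicity (vectorized).
#' @return Expected counts, one per `k`.
#' @export
poisson_binomial_expected_counts <- function(prob_matrix, k) {
  prob_matrix <- as.matrix(prob_matrix)
  tails <- matrix(0, nrow(prob_matrix), length(k))
  for (i in seq_len(nrow(prob_matrix))) {
    dp <- poisson_binomial_pmf(prob_matrix[i, ])
    cum <- rev(cumsum(rev(dp)))
    tails[i, ] <- ifelse(k + 1L <= length(cum), cum[pmin(k + 1L, length(cum))], 0)
    tails[i, k + 1L > length(cum)] <- 0
  }
  colSums(tails)
}

#' Deletion-shuffle null model
#'
#' Re-places every observed deletion uniformly at random within its own
#' chromosome, preserving its length and patient label, re-runs deletion
#' hotspot clustering, and tallies hotspot counts per multiplicity. The
#' expectation reported per multiplicity is the median over iterations, and
#' the empirical p-value is the proportion of iterations with a count as
#' extreme or more extreme (>=) than the observed count.
#'
#' @param deletions `data.table` with `patient, chrom, start, end`
#'   (DEL rows of a `mutation_table`).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param n_iter Number of shuffles (default 10000).
#' @param seed Integer RNG seed.
#' @param k_max Largest multiplicity tracked individually (default 10).
#' @param observed Optional named vector of observed per-k hotspot counts;
#'   defaults to the counts in `deletions` itself.
#' @return `data.table(k, expected_median, observed, p_value)`.
#' @export
shuffle_deletion_null <- function(deletions, chrom_lengths, n_iter = 10000L,
                                  seed = 1L, k_max = 10L, observed = NULL) {
  deletions <- as.data.table(deletions)
  ks <- 2L:k_max
  if (nrow(deletions) == 0) {
    return(data.table(k = ks, expected_median = 0, observed = 0L,
                      p_value = 1))
  }
  deletions[, width := end - start]
  if (any(deletions$width > chrom_lengths[deletions$chrom])) {
    stop("deletion longer than its chromosome")
  }
  if (is.null(observed)) {
    obs_hs <- detect_deletion_hotspots(
      as_mutation_table(deletions[, .(patient, cohort = "c", chrom, start,
                                      end, mut_type = "DEL", ref = "",
                                      alt = "")]))$hotspots
    observed <- tabulate_multiplicity(obs_hs$multiplicity, k_max)
  }
  set.seed(seed)
  counts <- matrix(0L, n_iter, length(ks))
  lens <- chrom_lengths[deletions$chrom]
  for (it in seq_len(n_iter)) {
    new_start <- floor(runif(nrow(deletions)) * (lens - deletions$width + 1))
    shuf <- data.table(patient = deletions$patient, cohort = "c",
                       chrom = deletions$chrom,
                       start = as.integer(new_start),
                       end = as.integer(new_start + deletions$width),
                       mut_type = "DEL", ref = "", alt = "")
    hs <- detect_deletion_hotspots(as_mutation_table(shuf))$hotspots
    counts[it, ] <- tabulate_multiplicity(hs$multiplicity, k_max)
  }
  med <- apply(counts, 2, median)
  pv <- vapply(seq_along(ks), function(j) {
    mean(counts[, j] >= observed[j])
  }, numeric(1))
  data.table(k = ks, expected_median = med, observed = as.integer(observed),
             p_value = pv)
}

tabulate_multiplicity <- function(mult, k_max) {
  ks <- 2L:k_max
  out <- integer(length(ks))
  for (j in seq_along(ks)) {
    out[j] <- if (ks[j] < k_max) sum(mult == ks[j]) else sum(mult >= k_max)
  }
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment
#' (`stats::p.adjust(method = "BH")`).
#'
#' @param p_values Numeric vector in `[0, 1]` (NAs passed through).
#' @return q-values, same length.
#' @export
bh_adjust <- function(p_values) {
  p.adjust(p_values, method = "BH")
}

#' Per-multiplicity null-expectation table for point hotspots
#'
#' Compares the observed hotspot multiplicity spectrum with the uniform
#' binomial model. Two false-discovery measures are emitted per cumulative
#' multiplicity class `>= k`: `fdr_expected_observed`, the ratio of expected
#' to observed cumulative counts capped at 1 (this equals the
#' Benjamini-Hochberg q-value of the per-site binomial p-value at the class
#' boundary, since all sites with multiplicity `>= k` share the same
#' per-site p-value), and `q_value`, a BH adjustment over per-class Poisson
#' tail p-values `P(Poisson(E_k) >= O_k)`.
#'
#' @param multiplicities Integer vector of per-hotspot multiplicities (all
#'   detected hotspots of one type).
#' @param genome_length,n_patients,total_mutations Model parameters.
#' @param k_max Largest class (default 10; last class is cumulative).
#' @return `data.table(k, expected, observed, p_value, q_value,
#'   fdr_expected_observed)` where `expected`/`observed` are cumulative
#'   (`>= k`) counts.
#' @export
null_expectation_table <- function(multiplicities, genome_length, n_patients,
                                   total_mutations, k_max = 10L) {
  ks <- 2L:k_max
  obs <- vapply(ks, function(kk) sum(multiplicities >= kk), integer(1))
  expd <- binomial_expected_counts(genome_length, n_patients,
                                   total_mutations, ks, mode = "ge")
  pv <- ppois(pmax(obs - 1L, 0L), expd, lower.tail = FALSE)
  pv[obs == 0] <- 1
  data.table(k = ks, expected = expd, observed = obs, p_value = pv,
             q_value = bh_adjust(pv),
             fdr_expected_observed = pmin(1, ifelse(obs > 0, expd / obs, NA)))
}
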