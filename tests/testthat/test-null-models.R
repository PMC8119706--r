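test_that("uniform binomial expected counts match closed form", {
  # L=100, N=10, M=100 -> p = 0.1; sites with >= 2 mutated patients
  closed <- 100 * (1 - 0.9^10 - 10 * 0.1 * 0.9^9)
  expect_equal(binomial_expected_counts(100, 10, 100, 2), closed,
               tolerance = 1e-12)
  expect_equal(round(closed, 2), 26.39)

  # k = 0: L * (1-p)^N, tending to L as p -> 0
  expect_equal(binomial_expected_counts(100, 10, 100, 0), 100)
  expect_lt(abs(binomial_expected_counts(1e6, 10, 1, 0, mode = "eq") -
                  1e6 * (1 - 1e-7)^10), 1e-3)

  # exact-k expectations sum to L over k = 0..N
  expect_equal(sum(binomial_expected_counts(1000, 8, 160, 0:8, mode = "eq")),
               1000, tolerance = 1e-9)

  # Monte-Carlo cross-check under the model: each patient-site pair is
  # mutated independently with probability p = M / (N * L) = 0.1
  set.seed(11)
  sims <- replicate(400, {
    m <- matrix(rbinom(1000, 1, 0.1), 100, 10)
    sum(rowSums(m) >= 2)
  })
  expect_lt(abs(mean(sims) - closed), 4 * sd(sims) / sqrt(length(sims)))

  expect_error(binomial_expected_counts(10, 2, 100, 2), "invalid")
})

test_that("genome-scale tails are computed accurately in log space", {
  e5 <- binomial_expected_counts(2.88e9, 2279, 30171668, 5)
  expect_gt(e5, 0)
  expect_lt(e5, 1e-2)
  # robust over plausible genome lengths
  for (L in c(2.5e9, 3.2e9)) {
    expect_lt(binomial_expected_counts(L, 2279, 30171668, 5), 1e-2)
  }
})

test_that("binomial site p-values match enumeration", {
  expect_equal(binomial_site_pvalue(10, 0.1, 0), 1)
  expect_equal(binomial_site_pvalue(2, 0.5, 2), 0.25)
  expect_equal(binomial_site_pvalue(10, 0.1, 2),
               1 - 0.9^10 - 10 * 0.1 * 0.9^9, tolerance = 1e-12)
  expect_error(binomial_site_pvalue(5, 0.1, 6), "k_observed")
})

test_that("Poisson-binomial tail is exact", {
  expect_equal(poisson_binomial_site_pvalue(c(0.5, 0.5), 2), 0.25)
  # full enumeration of 8 outcomes
  expect_equal(poisson_binomial_site_pvalue(c(0.1, 0.2, 0.3), 2),
               enumerate_poisbin_tail(c(0.1, 0.2, 0.3), 2),
               tolerance = 1e-15)
  expect_equal(round(poisson_binomial_site_pvalue(c(0.1, 0.2, 0.3), 2), 3),
               0.098)
  # random heterogeneous cases vs enumeration, N <= 15
  set.seed(3)
  for (rep in 1:10) {
    n <- sample(2:15, 1)
    pr <- runif(n)
    k <- sample.int(n, 1)
    expect_lt(abs(poisson_binomial_site_pvalue(pr, k) -
                    enumerate_poisbin_tail(pr, k)), 1e-12)
  }
  # homogeneous probabilities reduce to the binomial
  for (p in c(0.01, 0.3, 0.9)) {
    expect_equal(poisson_binomial_site_pvalue(rep(p, 12), 4),
                 binomial_site_pvalue(12, p, 4), tolerance = 1e-12)
  }
  expect_equal(sum(poisson_binomial_pmf(runif(20))), 1, tolerance = 1e-12)
  expect_error(poisson_binomial_site_pvalue(c(0.5, 1.2), 1), "\\[0, 1\\]")
})

test_that("per-site convolution expected counts match the uniform model", {
  m <- matrix(0.02, nrow = 50, ncol = 30)
  got <- poisson_binomial_expected_counts(m, 2:4)
  want <- 50 * pbinom(1:3, 30, 0.02, lower.tail = FALSE)
  expect_equal(unname(got), unname(want), tolerance = 1e-10)
})

test_that("deletion shuffle null matches exhaustive toy enumeration", {
  # two length-5 deletions on a 10 bp chromosome always overlap or abut
  dels <- mk_muts(c("P1", "P2"), "chr1", c(0L, 5L), "DEL",
                  end = c(5L, 10L), ref = "NNNNN")
  res <- shuffle_deletion_null(dels[, .(patient, cohort, chrom, start, end)],
                               c(chr1 = 10), n_iter = 200, seed = 5)
  expect_equal(res[k == 2]$expected_median, 1)
  expect_equal(res[k == 2]$p_value, 1)  # observed count 1 <= every iteration

  # exhaustive check: all 6x6 placements of two length-5 deletions in 10 bp
  # produce one cluster (max gap is 0 at the extreme placement 0/5)
  count2 <- 0
  for (s1 in 0:5) for (s2 in 0:5) {
    merged <- (s1 <= s2 + 5) && (s2 <= s1 + 5)
    count2 <- count2 + merged
  }
  expect_equal(count2, 36)  # every placement forms a multiplicity-2 cluster

  # empty input: medians 0, p 1
  res0 <- shuffle_deletion_null(dels[0], c(chr1 = 10), n_iter = 10, seed = 1)
  expect_true(all(res0$expected_median == 0))
  expect_true(all(res0$p_value == 1))

  # fixed seed reproducibility
  r1 <- shuffle_deletion_null(dels[, .(patient, cohort, chrom, start, end)],
                              c(chr1 = 10), n_iter = 50, seed = 9)
  r2 <- shuffle_deletion_null(dels[, .(patient, cohort, chrom, start, end)],
                              c(chr1 = 10), n_iter = 50, seed = 9)
  expect_identical(r1, r2)

  expect_error(shuffle_deletion_null(
    mk_muts("P1", "chr1", 0L, "DEL", end = 50L,
            ref = "N")[, .(patient, cohort, chrom, start, end)],
    c(chr1 = 10), n_iter = 5, seed = 1), "longer")
})

test_that("BH adjustment matches hand computation", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(8)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p rank
  expect_true(all(q >= p - 1e-12 | q == p))
  expect_true(all(q <= 1))
})

test_that("null expectation table reports both FDR estimators", {
  mult <- c(rep(2L, 50), rep(3L, 4), 5L)
  tab <- null_expectation_table(mult, genome_length = 1e5, n_patients = 20,
                                total_mutations = 2000)
  expect_equal(tab[k == 2]$observed, 55L)
  expect_equal(tab[k == 5]$observed, 1L)
  expect_true(all(tab$fdr_expected_observed <= 1, na.rm = TRUE))
  expect_equal(tab[k == 2]$expected,
               binomial_expected_counts(1e5, 20, 2000, 2), tolerance = 1e-12)
  # the class with a large excess has a small Poisson tail p
  expect_lt(tab[k == 5]$p_value, 1e-3)
})
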