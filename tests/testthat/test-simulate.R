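# small cohort for unit tests (full-size conditions are exercised in the
# acceptance suite)
small_config <- function(seed = 1L, n_noisy_sites = 4L, ...) {
  sim_config(seed = seed,
             chrom_lengths = c(chr1 = 3e5, chr2 = 2e5),
             n_patients = 60L, n_cohorts = 12L,
             n_snv = 6000L, n_del = 1500L, n_ins = 800L,
             gene_spacing = 10000L, n_homopolymers = 40L,
             n_slippage_hotspots = 8L, n_duplicate_pairs = 6L,
             n_noisy_sites = n_noisy_sites, ...)
}

test_that("same seed gives identical cohorts; different seeds differ", {
  s1 <- simulate_cohort(small_config(seed = 5))
  s2 <- simulate_cohort(small_config(seed = 5))
  expect_identical(s1$mutations, s2$mutations)
  expect_identical(s1$reference, s2$reference)
  expect_identical(s1$expression, s2$expression)
  s3 <- simulate_cohort(small_config(seed = 6))
  expect_false(identical(s1$mutations, s3$mutations))
})

test_that("planted drivers are recovered at their exact multiplicity", {
  sim <- simulate_cohort(small_config(seed = 11))
  snv <- detect_snv_hotspots(sim$mutations)
  for (j in which(sim$truth$drivers$mut_type == "SNV")) {
    d <- sim$truth$drivers[j]
    hit <- snv$hotspots[chrom == d$chrom & start == d$start]
    expect_equal(nrow(hit), 1)
    expect_gte(hit$multiplicity, d$multiplicity)  # background may add
  }
  # in the no-collision case multiplicity is exact: check patients
  d1 <- sim$truth$drivers[1]
  mem <- snv$members[chrom == d1$chrom & start == d1$start]
  expect_true(all(strsplit(d1$patients, ",")[[1]] %in% mem$patient))
})

test_that("driver-free configs yield no planted structure", {
  sim <- simulate_cohort(small_config(seed = 3, drivers = "none"))
  expect_equal(nrow(sim$truth$drivers), 0)
  expect_equal(nrow(sim$driver_sites), 0)
})

test_that("planted homopolymer runs are recorded truth", {
  sim <- simulate_cohort(small_config(seed = 2))
  runs <- sim$truth$homopolymer_runs
  planted <- sim$truth$planted_runs
  # every planted run is present as a maximal run with the same bounds
  found <- merge(planted, runs, by = c("chrom", "start", "end"))
  expect_equal(nrow(found), nrow(planted))
  # slippage artifacts sit on planted runs
  expect_gt(nrow(sim$truth$slippage_hotspots), 0)
})

test_that("generated VAFs realize the configured clonality within noise", {
  sim <- simulate_cohort(small_config(seed = 13))
  m <- as.data.table(sim$mutations)
  truth <- sim$truth$ccf
  cn_at <- copy_number_at(m[, .(patient, chrom, start)], sim$cn_segments)
  pur <- setNames(sim$purity$purity, sim$purity$patient)
  caf <- compute_caf(m$vaf, cn_at$copy_number, unname(pur[m$patient]))
  # mean recovered CAF tracks the generative cancer-cell fraction
  ok <- !is.na(caf)
  expect_lt(abs(mean(caf[ok] - truth$ccf[ok])), 0.02)
  # planted clonal drivers recover their shifted target
  drv <- which(!is.na(truth$driver_id))
  expect_gt(length(drv), 0)
  expect_lt(abs(mean(caf[drv] - truth$ccf[drv])), 0.05)
})

test_that("analytic per-k expectations match the closed form and realization", {
  # spec-sized single-region example: Binomial(100, 1e-4) tail over 1e4 sites
  cfg <- sim_config(chrom_lengths = c(chr1 = 1e4), n_patients = 100L,
                    n_snv = 100L, gene_spacing = 1e6)  # no genes fit: all bg
  e <- expected_hotspot_counts(cfg, "SNV", k = 2)
  p <- 1e-4
  closed <- 1e4 * (1 - (1 - p)^100 - 100 * p * (1 - p)^99)
  expect_equal(unname(e), closed, tolerance = 1e-9)
  expect_equal(round(closed, 2), 0.49)

  # zero rate everywhere -> zero expectation
  cfg0 <- sim_config(chrom_lengths = c(chr1 = 1e4), n_patients = 100L,
                     n_snv = 100L, gene_spacing = 1e6,
                     region_rates = setNames(
                       rep(0, 8),
                       c(region_hierarchy(), "intronic_intergenic")))
  expect_equal(unname(expected_hotspot_counts(cfg0, "SNV", 2)), 0)

  # realized hotspot counts agree with the expectation over seeds
  cfgS <- small_config(seed = 1, drivers = "none", n_noisy_sites = 0L)
  eS <- expected_hotspot_counts(cfgS, "SNV", k = 2)
  obs <- vapply(1:5, function(s) {
    simc <- small_config(seed = s, drivers = "none", n_noisy_sites = 0L)
    sim <- simulate_cohort(simc)
    nrow(detect_snv_hotspots(sim$mutations)$hotspots)
  }, numeric(1))
  expect_lt(abs(mean(obs) - eS), 4 * sqrt(eS / 5) + 2)
})

test_that("file emission writes the standard formats round-trippably", {
  dir <- file.path(tempdir(), "simout")
  sim <- simulate_cohort(small_config(seed = 4), out_dir = dir)
  expect_true(all(file.exists(file.path(dir, c(
    "reference.fa", "regions.bed", "genes.tsv", "mutations.tsv",
    "purity.tsv", "cn_segments.tsv", "expression.tsv",
    "noise_profile.tsv", "signatures.tsv")))))
  tab <- read_mutations(file.path(dir, "mutations.tsv"), "tsv")
  m0 <- as.data.table(sim$mutations)
  expect_equal(nrow(tab), nrow(m0))
  key <- function(x) sort(paste(x$patient, x$chrom, x$start, x$mut_type))
  expect_equal(key(tab), key(m0))
  regs <- read_regions_bed(file.path(dir, "regions.bed"))
  expect_equal(nrow(regs), nrow(sim$regions))
  genes <- read_gene_catalog(file.path(dir, "genes.tsv"))
  expect_equal(genes$gene_id, sim$genes$gene_id)
  ref <- Biostrings::readDNAStringSet(file.path(dir, "reference.fa"))
  expect_equal(as.character(ref[["chr1"]]), unname(sim$reference["chr1"]))
  unlink(dir, recursive = TRUE)
})

test_that("infeasible configs error", {
  expect_error(small_config(drivers = data.table(
    mut_type = "SNV", region_class = "promoter", cgc_class = "oncogene",
    classification = "noncoding", multiplicity = 500L, caf_shift = 0.3,
    expression_shift = 1)), "multiplicity")
})
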