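test_that("SNV hotspots pool differing alts and count distinct patients", {
  tab <- mk_muts(c("P1", "P2"), "chr1", c(100L, 100L), alt = c("T", "G"))
  res <- detect_snv_hotspots(tab)
  expect_equal(nrow(res$hotspots), 1)
  expect_equal(res$hotspots$multiplicity, 2L)
  expect_equal(res$hotspots$alts, "G,T")

  # singleton: no hotspot
  expect_equal(nrow(detect_snv_hotspots(mk_muts("P1", "chr1", 100L))$hotspots), 0)

  # same patient twice adds calls but not multiplicity
  tab2 <- mk_muts(c("P1", "P1", "P2"), "chr1", 100L, alt = c("T", "T", "G"))
  res2 <- detect_snv_hotspots(tab2)
  expect_equal(res2$hotspots$multiplicity, 2L)
  expect_equal(res2$hotspots$n_calls, 3L)
  # brute-force recount
  expect_equal(res2$hotspots$multiplicity,
               length(unique(tab2[start == 100L]$patient)))
})

test_that("insertion hotspots require the exact same boundary", {
  tab <- mk_muts(c("P1", "P2"), "chr1", 100L, "INS", alt = c("A", "TTG"))
  res <- detect_insertion_hotspots(tab)
  expect_equal(res$hotspots$multiplicity, 2L)

  adj <- mk_muts(c("P1", "P2"), "chr1", c(100L, 101L), "INS", alt = "A")
  expect_equal(nrow(detect_insertion_hotspots(adj)$hotspots), 0)

  three <- mk_muts(c("P1", "P2", "P3"), "chr1", 100L, "INS", alt = "A")
  expect_equal(detect_insertion_hotspots(three)$hotspots$multiplicity, 3L)
})

test_that("deletion clustering merges overlap and abutment but not gaps", {
  ov <- mk_muts(c("P1", "P2"), "chr1", c(10L, 14L), "DEL",
                end = c(15L, 20L), ref = "NNNNN")
  res <- detect_deletion_hotspots(ov)
  expect_equal(nrow(res$hotspots), 1)
  expect_equal(c(res$hotspots$start, res$hotspots$end), c(10L, 20L))

  abut <- mk_muts(c("P1", "P2"), "chr1", c(10L, 15L), "DEL",
                  end = c(15L, 20L), ref = "NNNNN")
  res2 <- detect_deletion_hotspots(abut)
  expect_equal(nrow(res2$hotspots), 1)
  expect_equal(c(res2$hotspots$start, res2$hotspots$end), c(10L, 20L))

  gap <- mk_muts(c("P1", "P2"), "chr1", c(10L, 16L), "DEL",
                 end = c(15L, 20L), ref = "NNNN")
  expect_equal(nrow(detect_deletion_hotspots(gap)$hotspots), 0)
})

test_that("deletion clustering equals brute-force connected components", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    start <- sample.int(500, n, replace = TRUE)
    width <- sample.int(10, n, replace = TRUE)
    tab <- mk_muts(paste0("P", seq_len(n)), "chr1", start, "DEL",
                   end = start + width, ref = "N")
    res <- detect_deletion_hotspots(tab, min_recurrence = 1L)
    got <- res$members[order(start, end, patient)]
    cl_expected <- brute_deletion_clusters(got$start, got$end)
    # same partition: cluster labels must be a bijection
    expect_equal(length(unique(got$hotspot_id)), length(unique(cl_expected)))
    expect_true(all(tapply(cl_expected, got$hotspot_id,
                           function(x) length(unique(x))) == 1))
  }
})

test_that("detection is order-invariant and conserves mutations", {
  set.seed(7)
  n <- 500
  tab <- mk_muts(sample(paste0("P", 1:30), n, TRUE), "chr1",
                 sample.int(300, n, TRUE))
  res1 <- detect_snv_hotspots(tab)
  res2 <- detect_snv_hotspots(tab[sample.int(n)])
  expect_equal(res1$hotspots, res2$hotspots)
  # conservation: members + singleton calls = all calls
  n_singletons <- nrow(tab) - nrow(res1$members)
  single_sites <- tab[, .(m = uniqueN(patient)), by = start][m < 2]
  expect_equal(n_singletons, nrow(tab[start %in% single_sites$start]))
})

test_that("duplicate same-patient indels are removed in both copies", {
  tab <- mk_muts(c("P1", "P1"), "chr1", c(10L, 11L), "DEL",
                 end = c(15L, 16L), ref = "NNNNN")
  out <- dedupe_indels(tab)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "n_removed"), 2L)

  # different patients are recurrence, not duplication
  tab2 <- mk_muts(c("P1", "P2"), "chr1", 10L, "DEL", end = 15L, ref = "NNNNN")
  expect_equal(nrow(dedupe_indels(tab2)), 2)

  # no duplicates -> identity
  tab3 <- mk_muts(c("P1", "P1"), "chr1", c(10L, 100L), "DEL",
                  end = c(15L, 105L), ref = "NNNNN")
  expect_equal(nrow(dedupe_indels(tab3)), 2)

  # SNVs never touched
  tab4 <- mk_muts(c("P1", "P1"), "chr1", c(10L, 10L))
  expect_equal(nrow(dedupe_indels(tab4)), 2)
})

test_that("homopolymer flag uses >= 9 bp runs including flanking bases", {
  ref <- mk_reference(chr1 = paste0("GC", strrep("A", 9), "GCGT"),
                      chr2 = paste0("GC", strrep("A", 8), "GCGT"))
  runs <- homopolymer_runs(ref)
  expect_equal(nrow(runs), 1)
  expect_equal(c(runs$start, runs$end), c(2L, 11L))

  # insertion inside the 9-A run
  expect_true(homopolymer_flag(data.table(chrom = "chr1", start = 5L,
                                          end = 5L), runs))
  # 8-A run: no flag
  expect_false(homopolymer_flag(data.table(chrom = "chr2", start = 5L,
                                           end = 5L), runs))
  # flanking base counts as bordering
  expect_true(homopolymer_flag(data.table(chrom = "chr1", start = 11L,
                                          end = 12L), runs))
  expect_false(homopolymer_flag(data.table(chrom = "chr1", start = 13L,
                                           end = 14L), runs))
})

test_that("noise score follows the log10(p+1) cohort sum and its filter scope", {
  prof0 <- data.table(chrom = "chr1", pos_1based = 101L, alt = "T",
                      cohort = c("a", "b"), percent = c(0, 0))
  expect_equal(noise_score(prof0, "T"), 0)

  prof <- data.table(chrom = "chr1", pos_1based = 101L, alt = "T",
                     cohort = c("a", "b"), percent = c(9, 99))
  expect_equal(noise_score(prof, "T"), 3)

  # ten cohorts at 99 percent -> score 20, not above 20, so kept
  prof10 <- data.table(chrom = "chr1", pos_1based = 101L, alt = "T",
                       cohort = paste0("c", 1:10), percent = 99)
  expect_equal(noise_score(prof10, "T"), 20)
  hs <- data.table(hotspot_id = "h1", chrom = "chr1", start = 100L,
                   end = 101L, mut_type = "SNV", multiplicity = 5L,
                   n_calls = 5L, alts = "T")
  res <- apply_noise_filter(hs, prof10)
  expect_equal(nrow(res$hotspots), 1)
  # push above 20 -> removed
  prof11 <- rbind(prof10, data.table(chrom = "chr1", pos_1based = 101L,
                                     alt = "T", cohort = "c11", percent = 9))
  res2 <- apply_noise_filter(hs, prof11)
  expect_equal(nrow(res2$hotspots), 0)
  expect_equal(res2$removed$noise_score, 21)

  # maximum over observed alts decides
  prof_two <- rbind(prof11, data.table(chrom = "chr1", pos_1based = 101L,
                                       alt = "G", cohort = "c1", percent = 0))
  expect_equal(noise_score(prof_two, c("T", "G")), 21)

  # unscored hotspots (no profile coverage) are retained
  hs2 <- copy(hs)[, `:=`(hotspot_id = "h2", start = 500L)]
  res3 <- apply_noise_filter(rbind(hs, hs2), prof11)
  expect_equal(res3$hotspots$hotspot_id, "h2")
  expect_true(is.na(res3$hotspots$noise_score))
})
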