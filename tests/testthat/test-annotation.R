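test_that("region assignment follows the priority hierarchy", {
  regions <- data.table(
    chrom = "chr1",
    start = c(100L, 100L, 300L),
    end = c(200L, 200L, 400L),
    region_class = c("protein_coding", "promoter", "enhancer"),
    gene_id = c("geneA", "geneB", "geneC"))
  genes <- mk_genes(c("geneA", "geneB", "geneC"), "chr1",
                    c(100L, 150L, 300L))
  hs <- data.table(chrom = "chr1", start = c(150L, 250L, 350L),
                   end = c(151L, 251L, 360L),
                   mut_type = c("SNV", "SNV", "DEL"))
  out <- assign_region(hs, regions, genes)
  expect_equal(out$region_class,
               c("protein_coding", "intronic_intergenic", "enhancer"))
  expect_equal(out$gene_id[1], "geneA")  # protein_coding beats promoter
  expect_equal(out$gene_distance[1], 0)
  expect_equal(out$region_class[2], "intronic_intergenic")
  expect_false(is.na(out$gene_id[2]))  # nearest-TSS fallback engaged
  # order of the interval table must not matter
  out2 <- assign_region(hs, regions[c(3, 1, 2)], genes)
  expect_equal(out$region_class, out2$region_class)
  # splice classes are merged in the report label
  regions2 <- data.table(chrom = "chr1", start = 100L, end = 200L,
                         region_class = "protein_splice_site",
                         gene_id = "geneA")
  expect_equal(assign_region(hs[1], regions2, genes)$region_class,
               "splice_site")
})

test_that("every hotspot gets exactly one region class (partition)", {
  set.seed(21)
  regions <- data.table(
    chrom = "chr1", start = as.integer(seq(0, 900, 100)),
    end = as.integer(seq(0, 900, 100) + sample(30:80, 10)),
    region_class = sample(region_hierarchy(), 10, TRUE),
    gene_id = paste0("g", 1:10))
  genes <- mk_genes(paste0("g", 1:10), "chr1", seq(0, 900, 100))
  hs <- data.table(chrom = "chr1", start = sample.int(1000, 200) - 1L)
  hs[, `:=`(end = start + 1L, mut_type = "SNV")]
  out <- assign_region(hs, regions, genes)
  expect_true(all(out$region_class %in% report_region_classes()))
  expect_equal(sum(table(out$region_class)), 200)
})

test_that("nearest TSS picks minimum distance with deterministic ties", {
  genes <- mk_genes(c("gA", "gB"), "chr1", c(50L, 300L))
  out <- nearest_tss("chr1", 100L, genes)
  expect_equal(out$gene_id, "gA")
  expect_equal(out$distance, 50)

  expect_equal(nearest_tss("chr1", 50L, genes)$distance, 0)

  # equidistant: lower coordinate wins
  genes2 <- mk_genes(c("gHigh", "gLow"), "chr1", c(150L, 50L))
  tie <- nearest_tss("chr1", 100L, genes2)
  expect_equal(tie$gene_id, "gLow")
  # same coordinate: lexicographic gene id
  genes3 <- mk_genes(c("gB", "gA"), "chr1", c(50L, 50L))
  expect_equal(nearest_tss("chr1", 100L, genes3)$gene_id, "gA")
  # brute-force check on random cases
  set.seed(4)
  gg <- mk_genes(paste0("g", 1:20), "chr1", sample.int(1000, 20))
  pos <- sample.int(1000, 50)
  got <- nearest_tss(rep("chr1", 50), pos, gg)
  for (i in seq_len(50)) {
    expect_equal(got$distance[i], min(abs(gg$tss - pos[i])))
  }
  expect_warning(nearest_tss("chrZ", 10L, gg), "no gene")
})

test_that("gene classification and driver-site flags", {
  genes <- mk_genes(c("gA", "gB"), "chr1", c(1L, 2L),
                    cgc_class = c("oncogene", "non_cancer"))
  hs <- data.table(chrom = "chr1", start = c(99L, 199L),
                   end = c(100L, 200L), mut_type = "SNV",
                   gene_id = c("gA", "gB"))
  out <- classify_gene(hs, genes,
                       driver_positions = data.table(chrom = "chr1",
                                                     pos_1based = 100L))
  expect_equal(out$cgc_class, c("oncogene", "non_cancer"))
  expect_equal(out$is_known_driver_site, c(TRUE, FALSE))
  # empty driver table -> all flags false
  out2 <- classify_gene(hs, genes, driver_positions = NULL)
  expect_false(any(out2$is_known_driver_site))
  # unknown gene -> non_cancer with warning
  hs3 <- copy(hs)[1, gene_id := "gZ"]
  expect_warning(out3 <- classify_gene(hs3, genes), "absent")
  expect_equal(out3$cgc_class[1], "non_cancer")
})

test_that("feature tracks annotate flags and scores with palindrome rule", {
  hs <- data.table(chrom = "chr1", start = c(10L, 100L), end = c(11L, 101L),
                   mut_type = "SNV", homopolymer = c(TRUE, FALSE))
  tracks <- list(
    self_chain = data.table(chrom = "chr1", start = 5L, end = 20L),
    palindrome_loop = data.table(chrom = "chr1", start = 0L, end = 200L),
    conservation = data.table(chrom = "chr1", start = c(0L, 50L),
                              end = c(50L, 200L), score = c(300, 500)))
  out <- annotate_features(hs, tracks)
  expect_true(out$self_chain[1]); expect_false(out$self_chain[2])
  # palindrome-loop suppressed where the homopolymer flag is set
  expect_false(out$palindrome_loop[1])
  expect_true(out$palindrome_loop[2])
  expect_equal(out$conservation_score, c(300, 500))
  # no tracks -> unchanged table
  expect_equal(names(annotate_features(hs, list())), names(hs))
})

test_that("PWM delta score reproduces hand arithmetic and symmetries", {
  m <- rbind(A = c(0.97, 0.01, 0.01, 0.01),
             C = c(0.01, 0.97, 0.01, 0.01),
             G = c(0.01, 0.01, 0.97, 0.01),
             T = c(0.01, 0.01, 0.01, 0.97))
  pwm <- t(m)  # positions x ACGT, consensus ACGT
  colnames(pwm) <- c("A", "C", "G", "T")
  # alt carries exact consensus, ref differs at the last motif base
  res <- pwm_delta_score("GGGACGALLL", "GGGACGTLLL", pwm, pseudocount = 0)
  expect_equal(res$best_alt, 4 * log2(0.97 / 0.25), tolerance = 1e-6)
  expect_equal(round(res$best_alt, 2), 7.82)
  expect_equal(res$best_ref, 3 * log2(0.97 / 0.25) + log2(0.01 / 0.25),
               tolerance = 1e-6)
  expect_equal(round(res$best_ref, 2), 1.22)
  expect_equal(round(res$delta, 2), 6.6)

  # identical windows -> delta 0
  expect_equal(pwm_delta_score("AACGTA", "AACGTA", pwm)$delta, 0)

  # reverse complement scores identically
  fwd <- pwm_delta_score("GGACGTGG", "GGACGTGG", pwm)$best_ref
  rc <- pwm_delta_score(revcomp("GGACGTGG"), revcomp("GGACGTGG"),
                        pwm)$best_ref
  expect_equal(fwd, rc, tolerance = 1e-12)

  # antisymmetry under swapping ref/alt
  a <- pwm_delta_score("GGGACGALLL", "GGGACGTLLL", pwm)
  b <- pwm_delta_score("GGGACGTLLL", "GGGACGALLL", pwm)
  expect_equal(a$delta, -b$delta, tolerance = 1e-12)
})

test_that("MEME-like PWM files parse into probability matrices", {
  path <- tempfile(fileext = ".meme")
  writeLines(c(
    "MEME version 4", "", "ALPHABET= ACGT", "",
    "MOTIF TEST_MOTIF", "letter-probability matrix: alength= 4 w= 2",
    "0.970000 0.010000 0.010000 0.010000",
    "0.010000 0.970000 0.010000 0.010000", ""
  ), path)
  pwms <- read_pwm_meme(path)
  expect_equal(names(pwms), "TEST_MOTIF")
  expect_equal(dim(pwms$TEST_MOTIF$matrix), c(2L, 4L))
  expect_equal(unname(pwms$TEST_MOTIF$matrix[1, "A"]), 0.97)
  expect_equal(unname(rowSums(pwms$TEST_MOTIF$matrix)), c(1, 1))
})
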