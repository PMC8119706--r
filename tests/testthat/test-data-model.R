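test_that("TSV reader converts 1-based positions and types variants", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "patient\tcohort\tchrom\tpos_1based\tref\talt\tvaf\tclassification",
    "P1\tc1\tchr1\t101\tA\tT\t0.4\tmissense",       # SNV
    "P2\tc1\tchr1\t101\tAT\tA\tNA\tunknown",        # anchored deletion of T
    "P3\tc1\tchr1\t101\tA\tAGG\tNA\tunknown",       # anchored insertion GG
    "P4\tc1\tchr1\t50\tACGTT\tAAA\tNA\tunknown"     # MNV -> skipped
  ), tsv)
  tab <- read_mutations(tsv, "tsv")
  expect_equal(nrow(tab), 3)
  expect_equal(attr(tab, "n_skipped_mnv"), 1L)
  snv <- tab[mut_type == "SNV"]
  expect_equal(c(snv$start, snv$end), c(100L, 101L))
  del <- tab[mut_type == "DEL"]
  expect_equal(c(del$start, del$end), c(101L, 102L))  # deleted base T
  expect_equal(del$ref, "T")
  ins <- tab[mut_type == "INS"]
  expect_equal(c(ins$start, ins$end), c(101L, 101L))
  expect_equal(ins$alt, "GG")
})

test_that("empty TSV gives an empty table", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines("patient\tcohort\tchrom\tpos_1based\tref\talt", tsv)
  expect_equal(nrow(read_mutations(tsv, "tsv")), 0)
})

test_that("VCF records are ingested with 1-based to 0-based conversion", {
  skip_if_not_installed("vcfR")
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=PATIENT,Number=1,Type=String,Description=\"p\">",
    "##INFO=<ID=COHORT,Number=1,Type=String,Description=\"c\">",
    "##INFO=<ID=ALT_READS,Number=1,Type=Integer,Description=\"a\">",
    "##INFO=<ID=REF_READS,Number=1,Type=Integer,Description=\"r\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t101\t.\tA\tT\t.\t.\tPATIENT=P1;COHORT=c1;ALT_READS=12;REF_READS=28",
    "chr1\t201\t.\tAT\tA\t.\t.\tPATIENT=P1;COHORT=c1;ALT_READS=5;REF_READS=25",
    "chr1\t301\t.\tA\tT,G\t.\t.\tPATIENT=P2;COHORT=c1;ALT_READS=9;REF_READS=21"
  ), vcf)
  tab <- read_mutations(vcf, "vcf")
  expect_equal(nrow(tab), 4)  # multi-allelic split into two SNVs
  snv1 <- tab[start == 100L]
  expect_equal(snv1$end, 101L)
  expect_equal(snv1$vaf, 12 / 40)
  expect_equal(tab[mut_type == "DEL"]$start, 201L)
  expect_equal(sum(tab$start == 300L), 2)
})

test_that("cohort filters drop excluded chroms/cohorts and are idempotent", {
  tab <- mk_muts(paste0("P", 1:10), c(rep("chr1", 6), rep("chrX", 4)),
                 1:10, cohort = c(rep("c1", 8), rep("Skin-Melanoma", 2)))
  expect_identical(nrow(apply_cohort_filters(tab)), 10L)
  f <- apply_cohort_filters(tab, excluded_chroms = "chrX")
  expect_equal(nrow(f), 6)
  f2 <- apply_cohort_filters(f, excluded_chroms = "chrX")
  expect_equal(f2, f)
  all_gone <- apply_cohort_filters(tab, excluded_cohorts = c("c1", "Skin-Melanoma"))
  expect_equal(nrow(all_gone), 0)
})

test_that("catalog writer emits 1-based positions and round-trips", {
  rows <- data.table(
    hotspot_id = paste0("h", 1:50), chrom = sample(c("chr1", "chr2"), 50, TRUE),
    start = sample.int(1000, 50), end = 0L,
    mut_type = sample(c("SNV", "INS", "DEL"), 50, TRUE),
    multiplicity = sample(2:9, 50, TRUE))
  rows[, end := ifelse(mut_type == "SNV", start + 1L,
                       ifelse(mut_type == "INS", start, start + 3L))]
  path <- tempfile(fileext = ".tsv")
  write_hotspot_catalog(rows, path)
  back <- read_hotspot_catalog(path)
  expect_equal(back[, .(hotspot_id, chrom, start, end, mut_type, multiplicity)],
               rows[, .(hotspot_id, chrom, start, end, mut_type, multiplicity)])
  # spot-check conventions: internal start 99 -> printed 100 for an SNV
  one <- data.table(hotspot_id = "h", chrom = "chr1", start = 99L,
                    end = 100L, mut_type = "SNV", multiplicity = 2L)
  write_hotspot_catalog(one, path)
  emitted <- fread(path)
  expect_equal(emitted$pos_start, 100L)
  # empty catalog -> header-only file
  write_hotspot_catalog(one[0], path)
  expect_equal(nrow(fread(path)), 0)
})

test_that("indel left-normalization shifts to the leftmost equivalent form", {
  # deleting either "A" of "CAAG" at positions 1 or 2 is the same variant
  ref <- mk_reference(chr1 = "CCAAG")
  tab <- mk_muts("P1", "chr1", 3L, "DEL", end = 4L, ref = "A", alt = "")
  norm <- normalize_indels(tab, ref)
  expect_equal(norm$start, 2L)
  expect_equal(norm$end, 3L)
  # oracle: applying either deletion to the sequence gives the same result
  apply_del <- function(s, start, end) {
    paste0(substr(s, 1, start), substr(s, end + 1, nchar(s)))
  }
  expect_equal(apply_del("CCAAG", 3, 4), apply_del("CCAAG", 2, 3))
  # insertion of "A" anywhere inside the A-run is equivalent
  tab2 <- mk_muts("P1", "chr1", 4L, "INS", end = 4L, ref = "", alt = "A")
  norm2 <- normalize_indels(tab2, ref)
  expect_equal(norm2$start, 2L)
  # SNVs untouched
  tab3 <- mk_muts("P1", "chr1", 3L, "SNV")
  expect_equal(normalize_indels(tab3, ref)$start, 3L)
})

test_that("mutation table invariants are enforced", {
  expect_error(as_mutation_table(data.table(
    patient = "P1", cohort = "c", chrom = "chr1", start = 5L, end = 7L,
    mut_type = "SNV", ref = "A", alt = "T")), "SNV")
  expect_error(as_mutation_table(data.table(
    patient = "P1", cohort = "c", chrom = "chr1", start = 5L, end = 5L,
    mut_type = "DEL", ref = "A", alt = "")), "DEL")
  # VAF derived from reads
  tab <- as_mutation_table(data.table(
    patient = "P1", cohort = "c", chrom = "chr1", start = 5L, end = 6L,
    mut_type = "SNV", ref = "A", alt = "T", alt_reads = 15, ref_reads = 45))
  expect_equal(tab$vaf, 0.25)
})
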