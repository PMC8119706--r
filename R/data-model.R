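#' Region hierarchy used for functional assignment
#'
#' The ordered priority used when a hotspot overlaps several functional
#' element classes: protein-coding sequence first, then protein-coding
#' splice-sites, 5' UTRs, 3' UTRs, promoters, non-coding splice-sites and
#' enhancers. Hotspots overlapping none of these are intronic/intergenic.
#' In reports the two splice classes are merged into a single `splice_site`
#' label.
#'
#' @return Character vector of region classes in priority order.
#' @export
region_hierarchy <- function() {
  c("protein_coding", "protein_splice_site", "UTR5", "UTR3",
    "promoter", "noncoding_splice_site", "enhancer")
}

#' Region classes as reported (splice classes merged)
#' @return Character vector of report-level region classes.
#' @export
report_region_classes <- function() {
  c("protein_coding", "splice_site", "UTR5", "UTR3", "promoter",
    "enhancer", "intronic_intergenic")
}

MUT_TYPES <- c("SNV", "INS", "DEL")
CLASSIFICATIONS <- c("missense", "nonsense", "synonymous", "splice",
                     "frameshift_indel", "inframe_indel", "noncoding",
                     "unknown")
CGC_CLASSES <- c("oncogene", "tsg", "other_cgc", "non_cancer")

MUTATION_COLS <- c("patient", "cohort", "chrom", "start", "end", "mut_type",
                   "ref", "alt", "vaf", "alt_reads", "ref_reads",
                   "classification")

#' Build a validated mutation table
#'
#' Canonical in-memory container for per-patient somatic calls: a
#' `data.table` with 0-based half-open coordinates and one row per call.
#' Checks the structural invariants (SNVs 1 bp, insertions zero-length,
#' deletions positive length; VAF consistent with read counts where both
#' are present).
#'
#' @param dt data.frame/data.table with the columns `patient, cohort, chrom,
#'   start, end, mut_type, ref, alt` and optionally `vaf, alt_reads,
#'   ref_reads, classification`.
#' @return A `data.table` with class `mutation_table`.
#' @export
as_mutation_table <- function(dt) {
  dt <- as.data.table(dt)
  for (col in c("vaf", "alt_reads", "ref_reads")) {
    if (!col %in% names(dt)) dt[, (col) := NA_real_]
  }
  if (!"classification" %in% names(dt)) dt[, classification := "unknown"]
  missing <- setdiff(MUTATION_COLS, names(dt))
  if (length(missing)) {
    stop("mutation table missing columns: ", paste(missing, collapse = ", "))
  }
  dt <- dt[, MUTATION_COLS, with = FALSE]
  dt[, `:=`(start = as.integer(start), end = as.integer(end),
            chrom = as.character(chrom), patient = as.character(patient),
            cohort = as.character(cohort))]
  if (nrow(dt)) {
    if (any(!dt$mut_type %in% MUT_TYPES)) stop("unknown mut_type")
    bad <- dt[mut_type == "SNV" & end != start + 1L]
    if (nrow(bad)) stop("SNV rows must have end == start + 1")
    bad <- dt[mut_type == "INS" & end != start]
    if (nrow(bad)) stop("INS rows must have end == start (zero-length anchor)")
    bad <- dt[mut_type == "DEL" & end <= start]
    if (nrow(bad)) stop("DEL rows must have end > start")
    # derive VAF from reads when absent
    dt[is.na(vaf) & !is.na(alt_reads) & !is.na(ref_reads) &
         (alt_reads + ref_reads) > 0,
       vaf := alt_reads / (alt_reads + ref_reads)]
  }
  setattr(dt, "class", c("mutation_table", class(dt)))
  dt[]
}

#' Read somatic mutation calls from TSV or VCF
#'
#' The TSV layout is one call per row with 1-based positions:
#' `patient, cohort, chrom, pos_1based, ref, alt, vaf, alt_reads, ref_reads,
#' classification` (the last four optional). VCF input (via the vcfR
#' package) expects per-record INFO tags `PATIENT`, `COHORT` and optionally
#' `ALT_READS`/`REF_READS`; multi-allelic records are split per alternate
#' allele. VCF-style anchored indels (`AT>A`, `A>AT`) are converted to the
#' internal representation, and multi-nucleotide substitutions are skipped
#' with a logged count (attribute `n_skipped_mnv`).
#'
#' @param path File path.
#' @param format `"tsv"` or `"vcf"`.
#' @return A `mutation_table`.
#' @export
read_mutations <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") read_mutations_tsv(path) else read_mutations_vcf(path)
}

read_mutations_tsv <- function(path) {
  dt <- fread(path, sep = "\t", colClasses = list(character = "chrom"))
  req <- c("patient", "cohort", "chrom", "pos_1based", "ref", "alt")
  missing <- setdiff(req, names(dt))
  if (length(missing)) {
    stop("mutation TSV missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(dt) == 0) {
    return(as_mutation_table(data.table(
      patient = character(), cohort = character(), chrom = character(),
      start = integer(), end = integer(), mut_type = character(),
      ref = character(), alt = character())))
  }
  bad <- which(is.na(dt$pos_1based) | dt$pos_1based < 1)
  if (length(bad)) stop("malformed position at line ", bad[1] + 1L)
  parsed <- classify_alleles(dt$pos_1based, dt$ref, dt$alt)
  n_mnv <- sum(parsed$mut_type == "MNV")
  keep_rows <- parsed$mut_type != "MNV"
  out <- data.table(
    patient = dt$patient, cohort = dt$cohort, chrom = dt$chrom,
    start = parsed$start, end = parsed$end, mut_type = parsed$mut_type,
    ref = parsed$ref, alt = parsed$alt
  )
  for (col in c("vaf", "alt_reads", "ref_reads")) {
    if (col %in% names(dt)) out[, (col) := as.numeric(dt[[col]])]
  }
  if ("classification" %in% names(dt)) out[, classification := dt$classification]
  out <- as_mutation_table(out[keep_rows])
  setattr(out, "n_skipped_mnv", n_mnv)
  out
}

# Convert 1-based anchored (VCF-style) or plain ref/alt pairs to internal
# typed coordinates. Returns MNV for multi-base substitutions.
classify_alleles <- function(pos_1based, ref, alt) {
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  ref[is.na(ref)] <- ""; alt[is.na(alt)] <- ""
  ref[ref %in% c(".", "-")] <- ""; alt[alt %in% c(".", "-")] <- ""
  nr <- nchar(ref); na <- nchar(alt)
  start <- integer(length(ref)); end <- integer(length(ref))
  type <- character(length(ref))
  oref <- ref; oalt <- alt
  for (i in seq_along(ref)) {
    p0 <- as.integer(pos_1based[i]) - 1L  # 0-based position of first ref base
    if (nr[i] == 1L && na[i] == 1L) {
      type[i] <- "SNV"; start[i] <- p0; end[i] <- p0 + 1L
    } else if (nr[i] > 1L && na[i] >= 1L && substr(ref[i], 1, na[i]) == alt[i]) {
      # anchored deletion: shared prefix, remaining ref bases deleted
      type[i] <- "DEL"
      start[i] <- p0 + na[i]; end[i] <- p0 + nr[i]
      oref[i] <- substr(ref[i], na[i] + 1L, nr[i]); oalt[i] <- ""
    } else if (na[i] > 1L && nr[i] >= 1L && substr(alt[i], 1, nr[i]) == ref[i]) {
      # anchored insertion after the shared prefix
      type[i] <- "INS"
      start[i] <- p0 + nr[i]; end[i] <- start[i]
      oalt[i] <- substr(alt[i], nr[i] + 1L, na[i]); oref[i] <- ""
    } else if (nr[i] >= 1L && na[i] == 0L) {
      # explicit deletion (ref bases given, no anchor)
      type[i] <- "DEL"; start[i] <- p0; end[i] <- p0 + nr[i]
    } else if (nr[i] == 0L && na[i] >= 1L) {
      # explicit insertion between pos-1 and pos
      type[i] <- "INS"; start[i] <- p0; end[i] <- p0
    } else {
      type[i] <- "MNV"; start[i] <- p0; end[i] <- p0 + nr[i]
    }
  }
  list(start = start, end = end, mut_type = type, ref = oref, alt = oalt)
}

read_mutations_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("vcfR is required to read VCF input")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.table(vcfR::getFIX(v))
  if (nrow(fx) == 0) {
    return(as_mutation_table(data.table(
      patient = character(), cohort = character(), chrom = character(),
      start = integer(), end = integer(), mut_type = character(),
      ref = character(), alt = character())))
  }
  info_tag <- function(tag) {
    x <- vcfR::extract.info(v, element = tag)
    if (is.null(x)) rep(NA_character_, nrow(fx)) else x
  }
  patient <- info_tag("PATIENT"); cohort <- info_tag("COHORT")
  altr <- suppressWarnings(as.numeric(info_tag("ALT_READS")))
  refr <- suppressWarnings(as.numeric(info_tag("REF_READS")))
  rows <- list(); n_mnv <- 0L
  for (i in seq_len(nrow(fx))) {
    alts <- strsplit(fx$ALT[i], ",", fixed = TRUE)[[1]]
    for (a in alts) {
      p <- classify_alleles(as.integer(fx$POS[i]), fx$REF[i], a)
      if (p$mut_type == "MNV") { n_mnv <- n_mnv + 1L; next }
      rows[[length(rows) + 1L]] <- data.table(
        patient = patient[i], cohort = cohort[i], chrom = fx$CHROM[i],
        start = p$start, end = p$end, mut_type = p$mut_type,
        ref = p$ref, alt = p$alt, vaf = NA_real_,
        alt_reads = altr[i], ref_reads = refr[i])
    }
  }
  out <- if (length(rows)) rbindlist(rows) else data.table(
    patient = character(), cohort = character(), chrom = character(),
    start = integer(), end = integer(), mut_type = character(),
    ref = character(), alt = character())
  out <- as_mutation_table(out)
  setattr(out, "n_skipped_mnv", n_mnv)
  out
}

#' Remove excluded cohorts and chromosomes
#'
#' Drops every call on an excluded chromosome or from an excluded cohort
#' (e.g. sex chromosomes and hypermutated cohorts such as melanoma and
#' lymphoid malignancies). Idempotent; an empty result is allowed.
#'
#' @param table A `mutation_table`.
#' @param excluded_cohorts,excluded_chroms Character vectors (may be empty).
#' @return Filtered `mutation_table`.
#' @export
apply_cohort_filters <- function(table, excluded_cohorts = character(),
                                 excluded_chroms = character()) {
  out <- table[!(chrom %in% excluded_chroms) & !(cohort %in% excluded_cohorts)]
  setattr(out, "class", class(table))
  out[]
}

#' Left-normalize indel calls against a reference genome
#'
#' Shifts each insertion/deletion to its leftmost equivalent representation
#' (the standard left-alignment used before comparing indel calls from
#' different callers), so representation differences become detectable by
#' the duplicate filter and deletion clustering is caller-independent.
#'
#' @param table A `mutation_table`.
#' @param reference Named list/character vector of chromosome sequences
#'   (plain uppercase strings), or a `Biostrings::DNAStringSet`.
#' @return The table with indels shifted; SNVs untouched.
#' @export
normalize_indels <- function(table, reference) {
  reference <- as_reference_list(reference)
  idx <- which(table$mut_type %in% c("INS", "DEL"))
  if (!length(idx)) return(table)
  tab <- copy(table)
  new_start <- tab$start; new_end <- tab$end
  new_ref <- tab$ref; new_alt <- tab$alt
  types <- tab$mut_type; chrs <- tab$chrom
  for (i in idx) {
    chr_seq <- reference[[chrs[i]]]
    if (is.null(chr_seq)) next
    if (types[i] == "DEL") {
      s <- new_start[i]; e <- new_end[i]
      # shift left while the base before the span equals the last deleted base
      while (s > 0L &&
             substr(chr_seq, s, s) == substr(chr_seq, e, e)) {
        s <- s - 1L; e <- e - 1L
      }
      if (s != new_start[i]) {
        new_ref[i] <- substr(chr_seq, s + 1L, e)
        new_start[i] <- s; new_end[i] <- e
      }
    } else {
      s <- new_start[i]; ins <- new_alt[i]; w <- nchar(ins)
      if (w > 0L) {
        while (s > 0L &&
               substr(chr_seq, s, s) == substr(ins, w, w)) {
          ins <- paste0(substr(chr_seq, s, s), substr(ins, 1L, w - 1L))
          s <- s - 1L
        }
      }
      new_start[i] <- s; new_end[i] <- s; new_alt[i] <- ins
    }
  }
  tab[, `:=`(start = new_start, end = new_end, ref = new_ref,
             alt = new_alt)]
  tab[]
}

as_reference_list <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    out <- as.list(as.character(reference))
  } else {
    out <- as.list(reference)
  }
  lapply(out, toupper)
}

#' Write the hotspot catalog to a tab-separated file
#'
#' Positions are emitted 1-based inclusive (`pos_start = start + 1`;
#' insertions are reported as the lower of the two base pairs they fall
#' between, i.e. `pos_start = start`, `pos_end = start + 1`). Round-trips
#' losslessly through [read_hotspot_catalog()].
#'
#' @param rows Catalog `data.table` (internal coordinates).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_hotspot_catalog <- function(rows, path) {
  rows <- as.data.table(rows)
  out <- copy(rows)
  if (nrow(out)) {
    out[, `:=`(pos_start = ifelse(mut_type == "INS", start, start + 1L),
               pos_end = ifelse(mut_type == "INS", start + 1L, end))]
  } else {
    out[, `:=`(pos_start = integer(), pos_end = integer())]
  }
  front <- intersect(c("hotspot_id", "chrom", "pos_start", "pos_end",
                       "mut_type", "multiplicity"), names(out))
  rest <- setdiff(names(out), c(front, "start", "end"))
  fwrite(out[, c(front, rest), with = FALSE], path, sep = "\t", na = "NA",
         quote = FALSE)
  invisible(path)
}

#' Read a hotspot catalog written by [write_hotspot_catalog()]
#' @param path File path.
#' @return `data.table` with internal 0-based half-open coordinates restored.
#' @export
read_hotspot_catalog <- function(path) {
  dt <- fread(path, sep = "\t", colClasses = list(character = "chrom"))
  if (nrow(dt)) {
    dt[, `:=`(start = ifelse(mut_type == "INS", pos_start, pos_start - 1L),
              end = ifelse(mut_type == "INS", pos_start, pos_end))]
    dt[, `:=`(start = as.integer(start), end = as.integer(end))]
  } else {
    dt[, `:=`(start = integer(), end = integer())]
  }
  dt[, c("pos_start", "pos_end") := NULL]
  dt[]
}

#' Read a BED6 region file into a region table
#'
#' The BED name field is `region_class:gene_id`. Coordinates stay 0-based
#' half-open (native BED convention).
#'
#' @param path BED file path.
#' @return `data.table(chrom, start, end, region_class, gene_id)`.
#' @export
read_regions_bed <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  if (nrow(dt) == 0) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), region_class = character(),
                      gene_id = character()))
  }
  setnames(dt, seq_len(min(4L, ncol(dt))),
           c("chrom", "start", "end", "name")[seq_len(min(4L, ncol(dt)))])
  parts <- tstrsplit(dt$name, ":", fixed = TRUE)
  data.table(chrom = as.character(dt$chrom), start = as.integer(dt$start),
             end = as.integer(dt$end),
             region_class = parts[[1]],
             gene_id = if (length(parts) > 1) parts[[2]] else NA_character_)
}

#' Read a gene catalog TSV
#'
#' Columns: `gene_id, chrom, tss, strand, cgc_class`, with `cgc_class` one
#' of `oncogene`, `tsg`, `other_cgc`, `non_cancer`. `tss` is 1-based.
#'
#' @param path TSV path.
#' @param n_genes_total,n_cgc_total Optional totals for the fold-change
#'   baseline; default to the counts in the file.
#' @return `data.table` with attributes `n_genes_total`, `n_cgc_total`.
#' @export
read_gene_catalog <- function(path, n_genes_total = NULL, n_cgc_total = NULL) {
  dt <- fread(path, sep = "\t", colClasses = list(character = "chrom"))
  stopifnot(all(c("gene_id", "chrom", "tss", "strand", "cgc_class") %in% names(dt)))
  if (any(!dt$cgc_class %in% CGC_CLASSES)) stop("unknown cgc_class in catalog")
  setattr(dt, "n_genes_total", n_genes_total %||% nrow(dt))
  setattr(dt, "n_cgc_total",
          n_cgc_total %||% sum(dt$cgc_class != "non_cancer"))
  dt[]
}

#' Read per-patient purity and copy-number segments
#'
#' Purity TSV: `patient, purity`. CN TSV: `patient, chrom, start, end,
#' copy_number` with 0-based half-open segments.
#'
#' @param purity_path,cn_path TSV paths.
#' @return List with `purity` (data.table) and `cn_segments` (data.table).
#' @export
read_purity_cn <- function(purity_path, cn_path) {
  pur <- fread(purity_path, sep = "\t")
  cn <- fread(cn_path, sep = "\t", colClasses = list(character = "chrom"))
  stopifnot(all(c("patient", "purity") %in% names(pur)))
  stopifnot(all(c("patient", "chrom", "start", "end", "copy_number") %in% names(cn)))
  list(purity = pur[], cn_segments = cn[])
}

#' Read an expression matrix (genes x patients) from TSV
#' @param path TSV with first column `gene_id`, remaining columns patients.
#' @return Numeric matrix with gene rownames and patient colnames.
#' @export
read_expression_matrix <- function(path) {
  dt <- fread(path, sep = "\t")
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- dt[[1]]
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
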