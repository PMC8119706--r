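#' Synthetic-cohort configuration
#'
#' Defines the generative conditions for a toy multi-cohort somatic
#' mutation dataset: a two-chromosome reference with planted homopolymer
#' runs, a gene/region layout with a functional-element hierarchy,
#' background SNV/indel rates, slippage-indel artifacts, duplicate indel
#' calls, noisy recurrent sites with a matching noise profile, planted
#' driver hotspots with elevated clonality and expression effects,
#' per-patient purity and copy-number events, per-cohort expression, and
#' per-mutation signature probabilities.
#'
#' Defaults: a 10 Mb genome (6 + 4 Mb chromosomes), 200 patients in 12
#' cohorts, 100,000 SNVs / 20,000 deletions / 10,000 insertions (a
#' deliberately elevated per-bp rate that compresses genome-scale hotspot
#' statistics into a desk-scale toy), uniform relative rates across
#' regions, 60x read depth, passenger clonality Uniform(0.4, 0.7) so a
#' +0.3 driver CAF shift keeps VAF at or below 1, purity Uniform(0.3,
#' 0.95).
#'
#' @param seed Integer seed; every stochastic step derives from it.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param n_patients,n_cohorts Cohort sizes.
#' @param n_snv,n_del,n_ins Background totals per mutation type.
#' @param region_rates Named relative per-bp rate multipliers per region
#'   class (1 = uniform).
#' @param gene_spacing Distance between consecutive gene starts (bp).
#' @param n_homopolymers,homopolymer_len Planted homopolymer runs (count,
#'   length range).
#' @param slippage_fraction Fraction of background indels relocated onto
#'   homopolymer runs (replication-slippage enrichment).
#' @param n_slippage_hotspots Planted recurrent slippage indel artifacts.
#' @param n_duplicate_pairs Planted same-patient duplicate indel pairs.
#' @param n_noisy_sites Planted recurrent SNV artifacts with a noisy
#'   profile (Eq-style score above the removal threshold).
#' @param drivers `data.table`/data.frame of planted drivers with columns
#'   `mut_type, region_class, cgc_class, classification, multiplicity,
#'   caf_shift, expression_shift`; `NULL` for the default panel,
#'   `"none"` for a driver-free cohort.
#' @param depth Sequencing depth for read sampling.
#' @param passenger_ccf Range of passenger cancer-cell fractions.
#' @param purity_range Tumor purity range.
#' @param cn_event_rate Mean copy-number events per patient.
#' @param cn_segment_length Length of each CN event (bp).
#' @param expression_sd Within-(gene, cohort) expression noise sd.
#' @return Config list (class `sim_config`).
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 6e6, chr2 = 4e6),
                       n_patients = 200L,
                       n_cohorts = 12L,
                       n_snv = 100000L,
                       n_del = 20000L,
                       n_ins = 10000L,
                       region_rates = NULL,
                       gene_spacing = 60000L,
                       n_homopolymers = 300L,
                       homopolymer_len = c(9L, 15L),
                       slippage_fraction = 0.15,
                       n_slippage_hotspots = 30L,
                       n_duplicate_pairs = 20L,
                       n_noisy_sites = 8L,
                       drivers = NULL,
                       depth = 60L,
                       passenger_ccf = c(0.4, 0.7),
                       purity_range = c(0.3, 0.95),
                       cn_event_rate = 3,
                       cn_segment_length = 2e5,
                       expression_sd = 1) {
  if (is.null(region_rates)) {
    region_rates <- setNames(rep(1, length(region_hierarchy()) + 1L),
                             c(region_hierarchy(), "intronic_intergenic"))
  }
  if (is.null(drivers)) drivers <- default_driver_panel()
  if (identical(drivers, "none")) drivers <- default_driver_panel()[0]
  cfg <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
              n_patients = as.integer(n_patients),
              n_cohorts = as.integer(n_cohorts),
              n_snv = as.integer(n_snv), n_del = as.integer(n_del),
              n_ins = as.integer(n_ins),
              region_rates = region_rates, gene_spacing = gene_spacing,
              n_homopolymers = n_homopolymers,
              homopolymer_len = homopolymer_len,
              slippage_fraction = slippage_fraction,
              n_slippage_hotspots = n_slippage_hotspots,
              n_duplicate_pairs = n_duplicate_pairs,
              n_noisy_sites = n_noisy_sites,
              drivers = as.data.table(drivers), depth = depth,
              passenger_ccf = passenger_ccf, purity_range = purity_range,
              cn_event_rate = cn_event_rate,
              cn_segment_length = cn_segment_length,
              expression_sd = expression_sd)
  if (nrow(cfg$drivers) && any(cfg$drivers$multiplicity > n_patients)) {
    stop("planted multiplicity exceeds the number of patients")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Default planted-driver panel
#'
#' One driver per major functional class: coding missense in an oncogene,
#' coding nonsense in a tumor suppressor, a promoter and a 5' UTR hotspot,
#' an enhancer hotspot, a splice-site hotspot, and one coding frameshift
#' deletion hotspot. CAF shift +0.3 and a 1-sd expression effect (sign
#' follows the gene class: down for tumor suppressors).
#'
#' @return `data.table` of driver specifications.
#' @export
default_driver_panel <- function() {
  data.table(
    mut_type = c("SNV", "SNV", "SNV", "SNV", "SNV", "SNV", "DEL"),
    region_class = c("protein_coding", "protein_coding", "promoter",
                     "UTR5", "enhancer", "protein_splice_site",
                     "protein_coding"),
    cgc_class = c("oncogene", "tsg", "oncogene", "tsg", "oncogene",
                  "tsg", "tsg"),
    classification = c("missense", "nonsense", "noncoding", "noncoding",
                       "noncoding", "splice", "frameshift_indel"),
    multiplicity = c(8L, 6L, 6L, 5L, 4L, 5L, 4L),
    caf_shift = 0.3,
    expression_shift = 1
  )
}

# Deterministic gene/region layout over the toy chromosomes. All element
# intervals are pairwise disjoint; the protein_coding interval doubles as
# the gene body.
build_gene_layout <- function(chrom_lengths, gene_spacing) {
  genes <- list(); regions <- list(); gi <- 0L
  cgc_cycle <- c("oncogene", "tsg", "other_cgc")
  for (ci in seq_along(chrom_lengths)) {
    chr <- names(chrom_lengths)[ci]
    len <- chrom_lengths[[ci]]
    if (len < 20000L + gene_spacing) next  # chromosome too short for genes
    tss0 <- seq(10000L, len - 10000L, by = gene_spacing)  # 0-based TSS
    for (t in tss0) {
      gi <- gi + 1L
      gene <- sprintf("G%03d", gi)
      # every 14th gene is a cancer gene (~7%), class cycling
      cgc <- if (gi %% 14L == 0L) cgc_cycle[(gi %/% 14L) %% 3L + 1L] else "non_cancer"
      genes[[gi]] <- data.table(gene_id = gene, chrom = chr,
                                tss = t + 1L, strand = "+",
                                cgc_class = cgc)
      regions[[gi]] <- data.table(
        chrom = chr,
        start = t + c(-1000L, 0L, 200L, 210L, 1700L, 1710L, 5000L),
        end   = t + c(0L, 200L, 210L, 1700L, 1710L, 2210L, 5500L),
        region_class = c("promoter", "UTR5", "protein_splice_site",
                         "protein_coding", "noncoding_splice_site",
                         "UTR3", "enhancer"),
        gene_id = gene)
    }
  }
  if (!length(genes)) {
    genes <- data.table(gene_id = character(), chrom = character(),
                        tss = integer(), strand = character(),
                        cgc_class = character())
    regions <- data.table(chrom = character(), start = integer(),
                          end = integer(), region_class = character(),
                          gene_id = character())
    setattr(genes, "n_genes_total", 0L); setattr(genes, "n_cgc_total", 0L)
    return(list(genes = genes, regions = regions))
  }
  genes <- rbindlist(genes); regions <- rbindlist(regions)
  setattr(genes, "n_genes_total", nrow(genes))
  setattr(genes, "n_cgc_total", sum(genes$cgc_class != "non_cancer"))
  list(genes = genes[], regions = regions[])
}

#' Generate a synthetic cohort
#'
#' Builds every input the hotspot pipeline consumes, plus a
#' machine-readable truth set, reproducibly from the config seed. With
#' `out_dir` set, also writes the standard-format files (reference FASTA,
#' regions BED, genes / mutations / purity / CN / expression / noise
#' profile / signature TSVs).
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory.
#' @return List: `reference` (named character), `regions`, `genes`,
#'   `mutations` (a `mutation_table`), `purity`, `cn_segments`,
#'   `expression` (matrix), `cohorts` (patient -> cohort), `noise_profile`,
#'   `signature_profiles`, `driver_sites`, and `truth`.
#' @export
simulate_cohort <- function(config = sim_config(), out_dir = NULL) {
  set.seed(config$seed)
  cl <- config$chrom_lengths
  chroms <- names(cl)
  bases <- c("A", "C", "G", "T")

  # reference with planted homopolymer runs at recorded positions
  ref_vec <- lapply(cl, function(L) bases[sample.int(4L, L, replace = TRUE)])
  hp <- list()
  for (i in seq_len(config$n_homopolymers)) {
    chr <- sample(chroms, 1, prob = cl / sum(cl))
    w <- sample(config$homopolymer_len[1]:config$homopolymer_len[2], 1)
    s <- sample.int(cl[[chr]] - w - 2L, 1)  # 0-based start
    b <- sample(bases, 1)
    ref_vec[[chr]][(s + 1L):(s + w)] <- b
    # break up accidental extension so the run is exactly [s, s+w)
    ref_vec[[chr]][s] <- sample(setdiff(bases, b), 1)
    ref_vec[[chr]][s + w + 1L] <- sample(setdiff(bases, b), 1)
    hp[[i]] <- data.table(chrom = chr, start = s, end = s + w, base = b)
  }
  planted_runs <- rbindlist(hp)
  reference <- vapply(ref_vec, paste, character(1), collapse = "")
  runs <- homopolymer_runs_vec(ref_vec, min_run = 9L)

  layout <- build_gene_layout(cl, config$gene_spacing)
  genes <- layout$genes; regions <- layout$regions

  patients <- sprintf("P%03d", seq_len(config$n_patients))
  cohorts <- setNames(
    paste0("cohort", rep_len(seq_len(config$n_cohorts),
                             config$n_patients)), patients)

  offsets <- cumsum(c(0, cl))[seq_along(cl)]
  names(offsets) <- chroms
  total_len <- sum(cl)
  site_weights <- region_site_weights(config, regions, total_len, offsets)

  draw_positions <- function(n) {
    g <- sample_sites(n, total_len, site_weights)
    chrom_idx <- findInterval(g, offsets)  # offsets are 0-based left edges
    # g is a 0-based genome offset; convert to per-chromosome 0-based
    chr <- chroms[chrom_idx]
    data.table(chrom = chr, start = as.integer(g - offsets[chrom_idx]))
  }

  # --- background SNVs ---
  snv <- draw_positions(config$n_snv)
  snv[, patient := sample(patients, .N, replace = TRUE)]
  snv[, ref := base_at(ref_vec, chrom, start)]
  snv[, alt := other_base(ref)]
  snv[, `:=`(end = start + 1L, mut_type = "SNV")]

  # --- background deletions / insertions ---
  del <- draw_positions(config$n_del)
  del[, width := pmin(1L + rgeom_int(.N, 0.5), 20L)]
  del[, start := as.integer(pmin(start, cl[chrom] - width))]  # stay on-chromosome
  del[, patient := sample(patients, .N, replace = TRUE)]
  ins <- draw_positions(config$n_ins)
  ins[, patient := sample(patients, .N, replace = TRUE)]
  ins[, insert_len := pmin(1L + rgeom_int(.N, 0.6), 10L)]
  # slippage enrichment: relocate a fraction of indels onto homopolymers
  if (nrow(planted_runs)) {
    n_slip_del <- round(config$slippage_fraction * nrow(del))
    if (n_slip_del > 0) {
      ridx <- sample.int(nrow(planted_runs), n_slip_del, replace = TRUE)
      didx <- sample.int(nrow(del), n_slip_del)
      del$chrom[didx] <- planted_runs$chrom[ridx]
      del$start[didx] <- planted_runs$start[ridx] +
        sample(0:3, n_slip_del, replace = TRUE)
      del$width[didx] <- 1L
    }
    n_slip_ins <- round(config$slippage_fraction * nrow(ins))
    if (n_slip_ins > 0) {
      ridx <- sample.int(nrow(planted_runs), n_slip_ins, replace = TRUE)
      iidx <- sample.int(nrow(ins), n_slip_ins)
      ins$chrom[iidx] <- planted_runs$chrom[ridx]
      ins$start[iidx] <- planted_runs$start[ridx] +
        sample(1:4, n_slip_ins, replace = TRUE)
      ins$insert_len[iidx] <- 1L
    }
  }
  del[, `:=`(end = start + width, mut_type = "DEL", alt = "")]
  del[, ref := substr_ref(ref_vec, chrom, start, end)]
  del[, width := NULL]
  ins[, alt := random_insert(ref_vec, chrom, start, insert_len)]
  ins[, `:=`(end = start, mut_type = "INS", ref = "")]
  ins[, insert_len := NULL]

  # --- planted recurrent slippage artifacts ---
  slip_truth <- list()
  if (config$n_slippage_hotspots > 0 && nrow(planted_runs)) {
    ridx <- sample.int(nrow(planted_runs),
                       min(config$n_slippage_hotspots, nrow(planted_runs)))
    extra <- list()
    for (j in seq_along(ridx)) {
      run <- planted_runs[ridx[j]]
      m <- sample(2:5, 1)
      pats <- sample(patients, m)
      extra[[j]] <- data.table(chrom = run$chrom,
                               start = run$start + sample(0:2, m, replace = TRUE),
                               patient = pats)
      slip_truth[[j]] <- data.table(chrom = run$chrom, start = run$start,
                                    end = run$end, multiplicity = m)
    }
    extra <- rbindlist(extra)
    extra[, `:=`(end = start + 1L, mut_type = "DEL", alt = "")]
    extra[, ref := substr_ref(ref_vec, chrom, start, end)]
    del <- rbindlist(list(del, extra), use.names = TRUE)
  }
  slippage_hotspots <- rbindlist(slip_truth)

  # --- planted noisy recurrent SNV sites + noise profile ---
  noise_rows <- list(); noisy_truth <- list()
  cohort_names <- unique(unname(cohorts))
  if (config$n_noisy_sites > 0) {
    for (j in seq_len(config$n_noisy_sites)) {
      repeat {
        chr <- sample(chroms, 1, prob = cl / sum(cl))
        s <- sample.int(cl[[chr]] - 10L, 1)
        if (!homopolymer_flag(data.table(chrom = chr, start = s,
                                         end = s + 1L), runs)[1]) break
      }
      m <- sample(5:8, 1)
      pats <- sample(patients, m)
      rb <- base_at(ref_vec, chr, s)
      ab <- other_base(rb)[1]
      snv <- rbindlist(list(snv, data.table(
        chrom = chr, start = s, patient = pats, ref = rb, alt = ab,
        end = s + 1L, mut_type = "SNV")), use.names = TRUE)
      noise_rows[[j]] <- data.table(chrom = chr, pos_1based = s + 1L,
                                    alt = ab, cohort = cohort_names,
                                    percent = runif(length(cohort_names),
                                                    70, 100))
      noisy_truth[[j]] <- data.table(chrom = chr, start = s,
                                     multiplicity = m, alt = ab)
    }
  }
  noisy_sites <- rbindlist(noisy_truth)

  # --- planted drivers ---
  drv <- copy(config$drivers)
  driver_truth <- list(); driver_members <- list()
  if (nrow(drv)) {
    for (j in seq_len(nrow(drv))) {
      cand_genes <- genes[cgc_class == drv$cgc_class[j]]$gene_id
      if (!length(cand_genes)) stop("no gene of class ", drv$cgc_class[j])
      gene <- sample(cand_genes, 1)
      iv <- regions[gene_id == gene & region_class == drv$region_class[j]]
      if (nrow(iv) == 0) stop("gene lacks region ", drv$region_class[j])
      repeat {
        s <- iv$start[1] + sample.int(iv$end[1] - iv$start[1] - 2L, 1)
        if (drv$mut_type[j] != "SNV") {
          # plant indels in left-normalized (canonical) form so truth
          # coordinates match the pipeline's normalized representation
          chr_seq <- ref_vec[[iv$chrom[1]]]
          e <- s + 2L
          while (s > iv$start[1] && chr_seq[s] == chr_seq[e]) {
            s <- s - 1L; e <- e - 1L
          }
        }
        if (!homopolymer_flag(data.table(chrom = iv$chrom[1], start = s,
                                         end = s + 1L), runs)[1]) break
      }
      m <- drv$multiplicity[j]
      pats <- sample(patients, m)
      if (drv$mut_type[j] == "SNV") {
        rb <- base_at(ref_vec, iv$chrom[1], s)
        rows <- data.table(chrom = iv$chrom[1], start = s, end = s + 1L,
                           mut_type = "SNV", ref = rb,
                           alt = other_base(rep(rb, m)), patient = pats)
      } else if (drv$mut_type[j] == "DEL") {
        rows <- data.table(chrom = iv$chrom[1], start = s, end = s + 2L,
                           mut_type = "DEL",
                           ref = substr_ref(ref_vec, rep(iv$chrom[1], m),
                                            rep(s, m), rep(s + 2L, m)),
                           alt = "", patient = pats)
      } else {
        rows <- data.table(chrom = iv$chrom[1], start = s, end = s,
                           mut_type = "INS", ref = "",
                           alt = random_insert(ref_vec, rep(iv$chrom[1], m),
                                               rep(s, m),
                                               rep(2L, m)), patient = pats)
      }
      rows[, driver_id := j]
      driver_members[[j]] <- rows
      driver_truth[[j]] <- data.table(
        driver_id = j, chrom = iv$chrom[1], start = s,
        end = rows$end[1], mut_type = drv$mut_type[j], gene_id = gene,
        region_class = drv$region_class[j], cgc_class = drv$cgc_class[j],
        classification = drv$classification[j], multiplicity = m,
        caf_shift = drv$caf_shift[j],
        expression_shift = drv$expression_shift[j],
        patients = paste(pats, collapse = ","))
    }
  }
  drivers_truth <- if (length(driver_truth)) rbindlist(driver_truth) else
    data.table()

  # --- assemble mutation table ---
  base_cols <- c("patient", "chrom", "start", "end", "mut_type", "ref", "alt")
  muts <- rbindlist(list(snv[, base_cols, with = FALSE],
                         del[, base_cols, with = FALSE],
                         ins[, base_cols, with = FALSE]),
                    use.names = TRUE)
  muts[, driver_id := NA_integer_]
  if (length(driver_members)) {
    dm <- rbindlist(driver_members)
    muts <- rbindlist(list(muts, dm[, c(base_cols, "driver_id"),
                                    with = FALSE]), use.names = TRUE)
  }
  muts[, cohort := unname(cohorts[patient])]
  muts[, classification := classify_by_region(muts, regions)]
  if (nrow(drivers_truth)) {
    for (j in seq_len(nrow(drivers_truth))) {
      muts[driver_id == j, classification := drivers_truth$classification[j]]
    }
  }

  # --- duplicate indel pairs (same patient, 1 bp representation shift) ---
  dup_truth <- data.table()
  indel_idx <- which(muts$mut_type %in% c("DEL", "INS") & is.na(muts$driver_id))
  if (config$n_duplicate_pairs > 0 && length(indel_idx)) {
    didx <- sample(indel_idx, min(config$n_duplicate_pairs, length(indel_idx)))
    dups <- muts[didx]
    dups[, `:=`(start = start + 1L, end = end + 1L)]
    dups[mut_type == "DEL",
         ref := substr_ref(ref_vec, chrom, start, end)]
    muts <- rbindlist(list(muts, dups), use.names = TRUE)
    dup_truth <- muts[didx, .(patient, chrom, start, end, mut_type)]
  }

  # --- purity and copy number ---
  purity <- data.table(patient = patients,
                       purity = runif(config$n_patients,
                                      config$purity_range[1],
                                      config$purity_range[2]))
  cn_rows <- list()
  for (p in patients) {
    n_ev <- rpois(1, config$cn_event_rate)
    if (n_ev == 0) next
    chr <- sample(chroms, n_ev, replace = TRUE, prob = cl / sum(cl))
    # events never exceed a quarter of their chromosome
    seg_len <- pmin(config$cn_segment_length, floor(cl[chr] / 4))
    s <- vapply(seq_along(chr), function(j)
      sample.int(cl[[chr[j]]] - seg_len[j], 1), numeric(1))
    cn_rows[[p]] <- data.table(patient = p, chrom = chr,
                               start = as.integer(s),
                               end = as.integer(s + seg_len),
                               copy_number = sample(c(1, 3, 4), n_ev,
                                                    replace = TRUE))
  }
  cn_segments <- if (length(cn_rows)) rbindlist(cn_rows) else
    data.table(patient = character(), chrom = character(),
               start = integer(), end = integer(), copy_number = numeric())

  # --- clonality and reads ---
  muts[, ccf := runif(.N, config$passenger_ccf[1], config$passenger_ccf[2])]
  if (nrow(drivers_truth)) {
    for (j in seq_len(nrow(drivers_truth))) {
      muts[driver_id == j, ccf := ccf + drivers_truth$caf_shift[j]]
    }
  }
  cn_at <- copy_number_at(muts[, .(patient, chrom, start)], cn_segments)
  muts[, copy_number := cn_at$copy_number]
  pur_lut <- setNames(purity$purity, purity$patient)
  muts[, purity := unname(pur_lut[patient])]
  muts[, true_vaf := pmin(1, ccf * copy_number * purity /
                            (copy_number * purity + 2 * (1 - purity)))]
  muts[, alt_reads := rbinom(.N, config$depth, true_vaf)]
  muts[, ref_reads := config$depth - alt_reads]
  muts[, vaf := alt_reads / config$depth]

  truth_ccf <- muts[, .(patient, chrom, start, mut_type, ccf, driver_id)]
  mutation_table <- as_mutation_table(
    muts[, c(MUTATION_COLS), with = FALSE])
  # carry driver linkage as an attribute-free parallel truth table

  # --- expression ---
  gene_base <- rnorm(nrow(genes), sd = 0.5)
  coh_off <- setNames(rnorm(length(cohort_names), sd = 0.3), cohort_names)
  expr <- matrix(rnorm(nrow(genes) * config$n_patients,
                       sd = config$expression_sd),
                 nrow = nrow(genes), ncol = config$n_patients,
                 dimnames = list(genes$gene_id, patients))
  expr <- expr + gene_base + rep(coh_off[unname(cohorts[patients])],
                                 each = nrow(genes))
  if (nrow(drivers_truth)) {
    for (j in seq_len(nrow(drivers_truth))) {
      sign_j <- if (drivers_truth$cgc_class[j] == "tsg") -1 else 1
      pats <- strsplit(drivers_truth$patients[j], ",")[[1]]
      expr[drivers_truth$gene_id[j], pats] <-
        expr[drivers_truth$gene_id[j], pats] +
        sign_j * drivers_truth$expression_shift[j] * config$expression_sd
    }
  }

  # --- signature probabilities (two synthetic processes per cohort) ---
  sig_ids <- c("2", "5")
  mix <- setNames(seq(0.2, 0.8, length.out = length(cohort_names)),
                  cohort_names)
  snv_rows <- which(mutation_table$mut_type == "SNV")
  w <- mix[mutation_table$cohort[snv_rows]]
  jit <- runif(length(snv_rows), -0.1, 0.1)
  p2 <- pmin(pmax(w + jit, 0.01), 0.99)
  signature_profiles <- rbindlist(list(
    data.table(patient = mutation_table$patient[snv_rows],
               chrom = mutation_table$chrom[snv_rows],
               pos_1based = mutation_table$start[snv_rows] + 1L,
               alt = mutation_table$alt[snv_rows],
               signature_id = "2", probability = p2),
    data.table(patient = mutation_table$patient[snv_rows],
               chrom = mutation_table$chrom[snv_rows],
               pos_1based = mutation_table$start[snv_rows] + 1L,
               alt = mutation_table$alt[snv_rows],
               signature_id = "5", probability = 1 - p2)))

  noise_profile <- if (length(noise_rows)) rbindlist(noise_rows) else
    data.table(chrom = character(), pos_1based = integer(),
               alt = character(), cohort = character(), percent = numeric())

  driver_sites <- if (nrow(drivers_truth)) {
    drivers_truth[, .(chrom, pos_1based = start + 1L, gene_id)]
  } else data.table(chrom = character(), pos_1based = integer(),
                    gene_id = character())

  out <- list(reference = reference, regions = regions, genes = genes,
              mutations = mutation_table, purity = purity,
              cn_segments = cn_segments, expression = expr,
              cohorts = cohorts, noise_profile = noise_profile,
              signature_profiles = signature_profiles,
              driver_sites = driver_sites,
              truth = list(config = config, drivers = drivers_truth,
                           slippage_hotspots = slippage_hotspots,
                           noisy_sites = noisy_sites,
                           duplicates = dup_truth,
                           homopolymer_runs = runs,
                           planted_runs = planted_runs,
                           ccf = truth_ccf))
  if (!is.null(out_dir)) write_cohort(out, out_dir)
  out
}

# per-site sampling weights by region class; NULL when uniform
region_site_weights <- function(config, regions, total_len, offsets) {
  rates <- config$region_rates
  if (all(abs(rates - rates[[1]]) < 1e-12)) return(NULL)
  w <- rep(rates[["intronic_intergenic"]], total_len)
  for (i in seq_len(nrow(regions))) {
    g0 <- offsets[[regions$chrom[i]]]
    w[(g0 + regions$start[i] + 1L):(g0 + regions$end[i])] <-
      rates[[regions$region_class[i]]]
  }
  w
}

sample_sites <- function(n, total_len, weights = NULL) {
  if (is.null(weights)) {
    floor(runif(n) * total_len)  # 0-based genome offsets
  } else {
    sample.int(total_len, n, replace = TRUE, prob = weights) - 1L
  }
}

rgeom_int <- function(n, prob) {
  as.integer(stats::rgeom(n, prob))
}

# a random base different from the reference base (vectorized)
other_base <- function(ref) {
  bases <- c("A", "C", "G", "T")
  alt_mat <- t(vapply(bases, function(b) setdiff(bases, b), character(3)))
  idx <- match(ref, bases)
  idx[is.na(idx)] <- 1L
  alt_mat[cbind(idx, sample.int(3L, length(ref), replace = TRUE))]
}

base_at <- function(ref_vec, chrom, start0) {
  out <- character(length(chrom))
  for (chr in unique(chrom)) {
    i <- chrom == chr
    out[i] <- ref_vec[[chr]][start0[i] + 1L]
  }
  out
}

substr_ref <- function(ref_vec, chrom, start0, end0) {
  out <- character(length(chrom))
  for (j in seq_along(chrom)) {
    out[j] <- paste(ref_vec[[chrom[j]]][(start0[j] + 1L):end0[j]],
                    collapse = "")
  }
  out
}

random_insert <- function(ref_vec, chrom, start0, len) {
  vapply(len, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
}

# classification from the position's functional region
classify_by_region <- function(muts, regions) {
  cls <- rep("noncoding", nrow(muts))
  asg <- assign_region(muts[, .(chrom, start, end, mut_type)], regions,
                       genes = NULL)
  coding <- asg$region_class == "protein_coding"
  splice <- asg$region_class == "splice_site"
  is_indel <- muts$mut_type != "SNV"
  cls[coding & !is_indel] <- sample(c("missense", "synonymous", "nonsense"),
                                    sum(coding & !is_indel), replace = TRUE,
                                    prob = c(0.7, 0.2, 0.1))
  frame <- (muts$end - muts$start) %% 3L != 0L
  frame[muts$mut_type == "INS"] <- nchar(muts$alt[muts$mut_type == "INS"]) %% 3L != 0L
  cls[coding & is_indel & frame] <- "frameshift_indel"
  cls[coding & is_indel & !frame] <- "inframe_indel"
  cls[splice] <- "splice"
  cls
}

#' Match planted drivers to detected hotspot / catalog rows
#'
#' Point hotspots (SNV, insertion) match on exact position and type;
#' deletion hotspots match on span overlap, since a detected cluster may
#' extend beyond the planted span when background deletions merge into it.
#'
#' @param drivers Truth driver table (`chrom, start, end, mut_type`).
#' @param rows Hotspot or catalog table (`chrom, start, end, mut_type`).
#' @param slack Extra bp allowed around deletion spans, absorbing
#'   normalization shifts of cluster members (default 5).
#' @return Integer row index into `rows` per driver (NA when absent).
#' @export
match_planted_drivers <- function(drivers, rows, slack = 5L) {
  drivers <- as.data.table(drivers); rows <- as.data.table(rows)
  vapply(seq_len(nrow(drivers)), function(j) {
    d <- drivers[j]
    if (d$mut_type == "DEL") {
      hit <- which(rows$mut_type == "DEL" & rows$chrom == d$chrom &
                     rows$start < d$end + slack &
                     rows$end > d$start - slack)
    } else {
      hit <- which(rows$mut_type == d$mut_type & rows$chrom == d$chrom &
                     rows$start == d$start)
    }
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
}

#' Analytic per-multiplicity hotspot expectations for a config
#'
#' Closed-form binomial expectations per region class: within each class,
#' sites share the per-patient probability implied by the class rate, and
#' the expected count of sites with at least `k` mutated patients is the
#' class length times the binomial tail. Sums over classes.
#'
#' @param config A [sim_config()].
#' @param mut_type `"SNV"`, `"INS"`, or `"DEL"` (total count selector;
#'   deletions are treated as points, an approximation used only for
#'   rough comparisons).
#' @param k Multiplicity vector.
#' @return Named numeric vector of expected at-least-k site counts.
#' @export
expected_hotspot_counts <- function(config, mut_type = "SNV", k = 2:10) {
  total <- switch(mut_type, SNV = config$n_snv, INS = config$n_ins,
                  DEL = config$n_del)
  layout <- build_gene_layout(config$chrom_lengths, config$gene_spacing)
  L_total <- sum(config$chrom_lengths)
  reg_len <- layout$regions[, .(len = sum(end - start)), by = region_class]
  lens <- setNames(reg_len$len, reg_len$region_class)
  lens["intronic_intergenic"] <- L_total - sum(reg_len$len)
  rates <- config$region_rates[names(lens)]
  denom <- sum(rates * lens)
  if (denom <= 0) return(setNames(numeric(length(k)), paste0("k", k)))
  N <- config$n_patients
  per_patient <- total / N
  out <- setNames(numeric(length(k)), paste0("k", k))
  for (r in names(lens)) {
    p_site <- per_patient * rates[[r]] / denom
    if (p_site <= 0) next
    out <- out + exp(log(lens[[r]]) +
                       pbinom(k - 1, N, p_site, lower.tail = FALSE,
                              log.p = TRUE))
  }
  out
}

# write all standard-format files for a simulated cohort
write_cohort <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dna <- Biostrings::DNAStringSet(sim$reference)
  Biostrings::writeXStringSet(dna, file.path(out_dir, "reference.fa"))
  reg <- copy(sim$regions)
  reg[, name := paste0(region_class, ":", gene_id)]
  fwrite(reg[, .(chrom, start, end, name, score = 0, strand = "+")],
         file.path(out_dir, "regions.bed"), sep = "\t", col.names = FALSE)
  fwrite(sim$genes, file.path(out_dir, "genes.tsv"), sep = "\t")
  m <- as.data.table(sim$mutations)
  fwrite(m[, .(patient, cohort, chrom, pos_1based = start + 1L,
               ref, alt, vaf, alt_reads, ref_reads, classification)],
         file.path(out_dir, "mutations.tsv"), sep = "\t")
  fwrite(sim$purity, file.path(out_dir, "purity.tsv"), sep = "\t")
  fwrite(sim$cn_segments, file.path(out_dir, "cn_segments.tsv"), sep = "\t")
  expr <- data.table(gene_id = rownames(sim$expression))
  expr <- cbind(expr, as.data.table(sim$expression))
  fwrite(expr, file.path(out_dir, "expression.tsv"), sep = "\t")
  fwrite(sim$noise_profile, file.path(out_dir, "noise_profile.tsv"),
         sep = "\t")
  fwrite(sim$signature_profiles, file.path(out_dir, "signatures.tsv"),
         sep = "\t")
  fwrite(sim$driver_sites, file.path(out_dir, "driver_sites.tsv"),
         sep = "\t")
  invisible(out_dir)
}
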