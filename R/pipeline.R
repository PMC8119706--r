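#' Pipeline run configuration
#'
#' Thresholds default to the study's working values: hotspot recurrence 2,
#' catalog inclusion at 4+ mutations for SNV hotspots and 2+ for indels
#' (the multiplicities at which the background models leave a false
#' discovery rate under 10%), FDR 10% for enrichment calls and 1% for the
#' CAF and expression group tests, noise filter on the top 1000 SNV
#' hotspots at score threshold 20, homopolymer minimum run 9 bp, delta-CAF
#' neighbor distance 2000 bp, 100,000 CAF permutations, 10,000 deletion
#' shuffles.
#'
#' @param seed Integer seed for all stochastic stages.
#' @param min_recurrence,snv_report_min,indel_report_min Recurrence
#'   thresholds.
#' @param fdr_inclusion,fdr_caf_expr FDR thresholds.
#' @param noise_top_k,noise_threshold Noise-filter scope and cutoff.
#' @param homopolymer_min_run Minimum homopolymer run (bp).
#' @param neighbor_min_dist Minimum delta-CAF neighbor distance (bp).
#' @param n_perm CAF permutation count.
#' @param shuffle_iters Deletion-shuffle iterations (0 disables the
#'   deletion null).
#' @param singleton_downsample Singleton downsampling fraction in the CAF
#'   permutation test.
#' @param excluded_chroms,excluded_cohorts Cohort-level exclusions.
#' @return Config list (class `run_config`).
#' @export
run_config <- function(seed = 1L, min_recurrence = 2L, snv_report_min = 4L,
                       indel_report_min = 2L, fdr_inclusion = 0.10,
                       fdr_caf_expr = 0.01, noise_top_k = 1000L,
                       noise_threshold = 20, homopolymer_min_run = 9L,
                       neighbor_min_dist = 2000L, n_perm = 100000L,
                       shuffle_iters = 10000L, singleton_downsample = 0.10,
                       excluded_chroms = character(),
                       excluded_cohorts = character()) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Run the full hotspot analysis pipeline
#'
#' Orchestrates ingest, indel normalization, duplicate removal, hotspot
#' detection for all three mutation types, homopolymer and noise filters,
#' null models, functional-region and cancer-gene annotation, region and
#' cancer-gene enrichment, delta-CAF clonality scores and permutation
#' tests, expression tests, signature attribution, and Fisher-method
#' ranking. Rerunning with the same inputs and config is bit-identical.
#'
#' @param inputs A list shaped like the output of [simulate_cohort()]:
#'   `mutations` (required), and optionally `reference`, `regions`,
#'   `genes`, `purity`, `cn_segments`, `expression`, `cohorts`,
#'   `noise_profile`, `signature_profiles`, `driver_sites`.
#' @param config A [run_config()].
#' @param out_dir Optional directory for the stage output tables.
#' @return A list of stage outputs: `catalog` (ranked), `hotspots` (per
#'   type, post-filter), `null_tables`, `region_enrichment`,
#'   `cgc_enrichment`, `second_hit`, `caf_permutation`,
#'   `expression_groups`, `mutation_annotation`, and `manifest` (stage
#'   record counts, thresholds, seed).
#' @export
run_pipeline <- function(inputs, config = run_config(), out_dir = NULL) {
  stopifnot(!is.null(inputs$mutations))
  manifest <- list(seed = config$seed,
                   thresholds = config[setdiff(names(config), "seed")])
  muts <- apply_cohort_filters(inputs$mutations, config$excluded_cohorts,
                               config$excluded_chroms)
  manifest$n_input <- nrow(inputs$mutations)
  manifest$n_after_cohort_filters <- nrow(muts)

  if (!is.null(inputs$reference)) {
    muts <- normalize_indels(muts, inputs$reference)
  }
  muts <- dedupe_indels(muts)
  manifest$n_duplicate_indels_removed <- attr(muts, "n_removed")

  chrom_lengths <- if (!is.null(inputs$reference)) {
    vapply(as_reference_list(inputs$reference), nchar, numeric(1))
  } else {
    tapply(muts$end, muts$chrom, max) * 1.0
  }
  genome_length <- sum(chrom_lengths)

  runs <- if (!is.null(inputs$homopolymer_runs)) {
    as.data.table(inputs$homopolymer_runs)
  } else if (!is.null(inputs$reference)) {
    homopolymer_runs(inputs$reference, config$homopolymer_min_run)
  } else data.table(chrom = character(), start = integer(),
                    end = integer(), base = character())

  # indel filters also apply to singleton indels
  indel_rows <- muts$mut_type %in% c("INS", "DEL")
  indel_hp <- rep(FALSE, nrow(muts))
  indel_hp[indel_rows] <- homopolymer_flag(
    muts[indel_rows, .(chrom, start, end)], runs)
  manifest$n_homopolymer_indel_calls <- sum(indel_hp)

  snv <- detect_snv_hotspots(muts, config$min_recurrence)
  ins <- detect_insertion_hotspots(muts, config$min_recurrence)
  del <- detect_deletion_hotspots(muts, config$min_recurrence)
  manifest$n_hotspots_detected <- c(SNV = nrow(snv$hotspots),
                                    INS = nrow(ins$hotspots),
                                    DEL = nrow(del$hotspots))

  # homopolymer filter: indel hotspots removed, SNV hotspots annotated
  for (nm in c("ins", "del")) {
    res <- get(nm)
    if (nrow(res$hotspots)) {
      flag <- homopolymer_flag(res$hotspots[, .(chrom, start, end)], runs)
      res$removed_homopolymer <- res$hotspots[flag]
      res$hotspots <- res$hotspots[!flag]
      res$members <- res$members[hotspot_id %in% res$hotspots$hotspot_id]
      assign(nm, res)
    }
  }
  manifest$n_homopolymer_hotspots_removed <-
    c(INS = nrow(ins$removed_homopolymer %||% data.table()),
      DEL = nrow(del$removed_homopolymer %||% data.table()))
  if (nrow(snv$hotspots)) {
    snv$hotspots[, homopolymer := homopolymer_flag(
      snv$hotspots[, .(chrom, start, end)], runs)]
  }

  nf <- apply_noise_filter(snv$hotspots, inputs$noise_profile,
                           config$noise_top_k, config$noise_threshold)
  snv$removed_noise <- nf$removed
  snv$hotspots <- nf$hotspots
  snv$members <- snv$members[hotspot_id %in% snv$hotspots$hotspot_id]
  manifest$n_noise_hotspots_removed <- nrow(nf$removed)

  # --- null models ---
  n_patients <- length(unique(muts$patient))
  null_tables <- list(
    SNV = null_expectation_table(snv$hotspots$multiplicity, genome_length,
                                 n_patients, sum(muts$mut_type == "SNV")),
    INS = null_expectation_table(ins$hotspots$multiplicity, genome_length,
                                 n_patients, sum(muts$mut_type == "INS")))
  if (config$shuffle_iters > 0 && sum(muts$mut_type == "DEL") > 0) {
    null_tables$DEL <- shuffle_deletion_null(
      muts[mut_type == "DEL", .(patient, cohort, chrom, start, end)],
      chrom_lengths, n_iter = config$shuffle_iters, seed = config$seed,
      observed = tabulate_multiplicity(del$hotspots$multiplicity, 10L))
  }

  # --- annotation of all mutations (drives singleton strata and
  #     wild-type sets) and of hotspots ---
  regions <- inputs$regions %||% data.table(
    chrom = character(), start = integer(), end = integer(),
    region_class = character(), gene_id = character())
  genes <- inputs$genes
  mut_ann <- assign_region(
    cbind(muts, data.table(row0 = seq_len(nrow(muts)))), regions, genes)
  mut_ann[, indel_homopolymer := indel_hp]
  hotspot_sets <- list(SNV = snv, INS = ins, DEL = del)
  member_ids <- lapply(hotspot_sets, function(x)
    if (nrow(x$members)) x$members[, .(patient, chrom, start, mut_type)]
    else data.table())
  all_members <- rbindlist(member_ids[vapply(member_ids, nrow, 1L) > 0])
  mut_ann[, in_hotspot := FALSE]
  if (nrow(all_members)) {
    key_m <- paste(all_members$patient, all_members$chrom,
                   all_members$start, all_members$mut_type)
    mut_ann[, in_hotspot := paste(patient, chrom, start, mut_type) %in% key_m]
  }

  # --- catalog row selection ---
  cat_rows <- rbindlist(list(
    snv$hotspots[multiplicity >= config$snv_report_min],
    ins$hotspots[multiplicity >= config$indel_report_min],
    del$hotspots[multiplicity >= config$indel_report_min]),
    use.names = TRUE, fill = TRUE)
  cat_rows <- assign_region(cat_rows, regions, genes)
  if (!is.null(genes)) {
    cat_rows <- classify_gene(cat_rows, genes, inputs$driver_sites)
  } else {
    cat_rows[, `:=`(cgc_class = "non_cancer", is_known_driver_site = FALSE)]
  }

  # --- CAF / delta-CAF ---
  caf_z <- rep(NA_real_, nrow(muts))
  if (!is.null(inputs$purity) && !is.null(inputs$cn_segments)) {
    cn_at <- copy_number_at(muts[, .(patient, chrom, start)],
                            inputs$cn_segments)
    pur <- setNames(inputs$purity$purity, inputs$purity$patient)
    caf <- compute_caf(muts$vaf, cn_at$copy_number, unname(pur[muts$patient]))
    coding_iv <- regions[region_class == "protein_coding"]
    dtab <- data.table(patient = muts$patient, chrom = muts$chrom,
                       start = muts$start, caf = caf)
    delta <- compute_delta_caf(dtab, coding_iv, config$neighbor_min_dist)
    caf_z <- zscore_normalize(delta)
  }
  mut_ann[, caf_z := caf_z]

  # --- per-hotspot delta-CAF p against matched singletons ---
  singles <- mut_ann[in_hotspot == FALSE]
  # singleton reference stratum: same functional region, same gene
  single_z <- split(singles$caf_z,
                    paste(singles$region_class, singles$gene_id))
  caf_p <- rep(NA_real_, nrow(cat_rows))
  caf_med <- rep(NA_real_, nrow(cat_rows))
  mut_key <- paste(mut_ann$patient, mut_ann$chrom, mut_ann$start,
                   mut_ann$mut_type)
  for (i in seq_len(nrow(cat_rows))) {
    hset <- hotspot_sets[[cat_rows$mut_type[i]]]
    mem <- hset$members[hotspot_id == cat_rows$hotspot_id[i]]
    hz <- mut_ann$caf_z[match(paste(mem$patient, mem$chrom, mem$start,
                                    mem$mut_type), mut_key)]
    caf_med[i] <- if (all(is.na(hz))) NA_real_ else
      median(hz, na.rm = TRUE)
    sz <- single_z[[paste(cat_rows$region_class[i], cat_rows$gene_id[i])]]
    caf_p[i] <- hotspot_caf_pvalue(hz, sz)
  }

  # --- expression ---
  expr_p <- rep(NA_real_, nrow(cat_rows))
  expr_med <- rep(NA_real_, nrow(cat_rows))
  expression_groups <- NULL
  if (!is.null(inputs$expression) && !is.null(inputs$cohorts)) {
    ez <- expression_zscores(inputs$expression, inputs$cohorts)
    wt <- wildtype_sets_fast(mut_ann, genes, regions, inputs$cn_segments,
                             names(inputs$cohorts))
    for (i in seq_len(nrow(cat_rows))) {
      g <- cat_rows$gene_id[i]
      if (is.na(g) || !g %in% rownames(ez)) next
      hset <- hotspot_sets[[cat_rows$mut_type[i]]]
      pats <- unique(hset$members[hotspot_id == cat_rows$hotspot_id[i]]$patient)
      hz <- ez[g, intersect(pats, colnames(ez))]
      wz <- ez[g, intersect(wt[[g]] %||% character(), colnames(ez))]
      if (length(hz)) expr_med[i] <- median(hz, na.rm = TRUE)
      expr_p[i] <- hotspot_expression_pvalue(hz, wz, cat_rows$cgc_class[i])
    }
    expression_groups <- expression_group_tests(cat_rows, hotspot_sets, ez,
                                                wt, config)
  }

  # --- signatures (SNV catalog rows) ---
  top_sigs <- rep(NA_character_, nrow(cat_rows))
  if (!is.null(inputs$signature_profiles) &&
      nrow(inputs$signature_profiles %||% data.table())) {
    for (i in which(cat_rows$mut_type == "SNV")) {
      mem <- hotspot_sets$SNV$members[hotspot_id == cat_rows$hotspot_id[i]]
      pr <- hotspot_signature_profile(mem, inputs$signature_profiles)
      if (!is.null(pr$profile)) {
        grp <- group_signatures(pr$profile)
        ts <- top_signatures(grp, 2L)
        top_sigs[i] <- paste(sprintf("%s(%.2f)", names(ts), ts),
                             collapse = ";")
      }
    }
  }

  # --- enrichments ---
  lens <- region_lengths(regions, chrom_lengths)
  enr <- list()
  for (grp in list(list(name = "SNV_hotspots",
                        dt = cat_rows[mut_type == "SNV"]),
                   list(name = "indel_hotspots",
                        dt = cat_rows[mut_type != "SNV"]),
                   list(name = "SNV_singletons",
                        dt = singles[mut_type == "SNV"]),
                   list(name = "indel_singletons",
                        dt = singles[mut_type != "SNV" &
                                       indel_homopolymer == FALSE]))) {
    counts <- table(factor(grp$dt$region_class,
                           levels = report_region_classes()))
    enr[[grp$name]] <- region_enrichment(
      setNames(as.integer(counts), names(counts)), lens)
  }

  cgc_enr <- NULL
  if (!is.null(genes)) {
    baseline <- attr(genes, "n_cgc_total") / attr(genes, "n_genes_total")
    cgc_enr <- rbindlist(lapply(
      setdiff(report_region_classes(), "intronic_intergenic"),
      function(rc) {
        rbindlist(lapply(c("SNV", "indel"), function(ty) {
          sub <- if (ty == "SNV") cat_rows[mut_type == "SNV" & region_class == rc]
          else cat_rows[mut_type != "SNV" & region_class == rc]
          res <- cgc_fold_change(sum(sub$cgc_class != "non_cancer"),
                                 nrow(sub), baseline)
          res[, `:=`(region = rc, mut_group = ty)]
          res
        }))
      }))
    cgc_enr[, q_value := bh_adjust(p_value)]
  }

  # --- second-hit missense test (gene regulatory hotspots vs singletons) ---
  reg_classes <- c("splice_site", "UTR5", "UTR3", "promoter", "enhancer")
  missense <- mut_ann[classification == "missense" &
                        region_class == "protein_coding",
                      .(patient, gene_id)]
  second_hit <- NULL
  reg_rows <- which(cat_rows$region_class %in% reg_classes)
  if (length(reg_rows) && nrow(missense)) {
    hs_hit <- logical(length(reg_rows))
    for (jj in seq_along(reg_rows)) {
      i <- reg_rows[jj]
      hset <- hotspot_sets[[cat_rows$mut_type[i]]]
      mem <- hset$members[hotspot_id == cat_rows$hotspot_id[i]]
      hs_hit[jj] <- any(paste(mem$patient, cat_rows$gene_id[i]) %in%
                          paste(missense$patient, missense$gene_id))
    }
    sing_reg <- singles[region_class %in% reg_classes &
                          !(mut_type != "SNV" & indel_homopolymer)]
    s_hit <- paste(sing_reg$patient, sing_reg$gene_id) %in%
      paste(missense$patient, missense$gene_id)
    second_hit <- second_hit_test(sum(hs_hit), sum(!hs_hit),
                                  sum(s_hit), sum(!s_hit))
  }

  # --- CAF permutation test over protein-coding groups ---
  caf_perm <- NULL
  if (config$n_perm > 0 && any(!is.na(mut_ann$caf_z))) {
    grp_lab <- caf_permutation_groups(mut_ann, cat_rows, hotspot_sets,
                                      genes)
    if (length(unique(na.omit(grp_lab))) >= 2) {
      caf_perm <- group_median_permutation_test(
        mut_ann$caf_z, grp_lab, n_perm = config$n_perm,
        singleton_downsample = config$singleton_downsample,
        seed = config$seed)
    }
  }

  catalog <- build_catalog(cat_rows, caf_p, expr_p, caf_med, expr_med)
  catalog[, top_signatures := top_sigs[match(hotspot_id,
                                             cat_rows$hotspot_id)]]
  manifest$n_catalog <- nrow(catalog)

  out <- list(catalog = catalog, hotspots = hotspot_sets,
              null_tables = null_tables, region_enrichment = enr,
              cgc_enrichment = cgc_enr, second_hit = second_hit,
              caf_permutation = caf_perm,
              expression_groups = expression_groups,
              mutation_annotation = mut_ann, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_hotspot_catalog(catalog, file.path(out_dir, "catalog.tsv"))
    for (nm in names(null_tables)) {
      fwrite(null_tables[[nm]], file.path(out_dir,
                                          paste0("null_", nm, ".tsv")),
             sep = "\t")
    }
    for (nm in names(enr)) {
      fwrite(enr[[nm]], file.path(out_dir,
                                  paste0("enrichment_", nm, ".tsv")),
             sep = "\t")
    }
    if (!is.null(cgc_enr)) fwrite(cgc_enr, file.path(out_dir, "cgc_enrichment.tsv"),
                                  sep = "\t")
    writeLines(paste(utils::capture.output(utils::str(manifest)),
                     collapse = "\n"),
               file.path(out_dir, "manifest.txt"))
  }
  out
}

# total bp extent per report region class (splice classes merged; the
# remainder of the genome is intronic/intergenic)
region_lengths <- function(regions, chrom_lengths) {
  lens <- setNames(numeric(length(report_region_classes())),
                   report_region_classes())
  if (nrow(regions)) {
    rr <- copy(as.data.table(regions))
    rr[region_class %in% c("protein_splice_site", "noncoding_splice_site"),
       region_class := "splice_site"]
    agg <- rr[, .(len = sum(end - start)), by = region_class]
    lens[agg$region_class] <- agg$len
  }
  lens["intronic_intergenic"] <- sum(chrom_lengths) -
    sum(lens[names(lens) != "intronic_intergenic"])
  lens
}

# fast wild-type sets from the per-mutation assignment table: a patient is
# disqualified for a gene by any direct-overlap mutation in its coding or
# regulatory (non-enhancer) intervals, or by a CN != 2 segment over the body
wildtype_sets_fast <- function(mut_ann, genes, regions, cn_segments,
                               patients) {
  excl <- mut_ann[region_class %in% c("protein_coding", "splice_site",
                                      "UTR5", "UTR3", "promoter") &
                    gene_distance == 0,
                  .(patient = unique(patient)), by = gene_id]
  bad <- split(excl$patient, excl$gene_id)
  if (!is.null(cn_segments) && nrow(cn_segments) && !is.null(genes)) {
    seg <- as.data.table(cn_segments)[copy_number != 2]
    bodies <- as.data.table(regions)[region_class == "protein_coding"]
    if (nrow(seg) && nrow(bodies)) {
      setkey(seg, chrom, start, end)
      q <- bodies[, .(chrom, start, end, gene_id)]
      setkey(q, chrom, start, end)
      ov <- foverlaps(q, seg, nomatch = NULL)
      if (nrow(ov)) {
        cnbad <- split(ov$patient, ov$gene_id)
        for (g in names(cnbad)) {
          bad[[g]] <- union(bad[[g]] %||% character(), cnbad[[g]])
        }
      }
    }
  }
  all_genes <- if (!is.null(genes)) genes$gene_id else names(bad)
  out <- lapply(setNames(all_genes, all_genes), function(g)
    setdiff(patients, bad[[g]] %||% character()))
  out
}

# group-level Wilcoxon expression tests, stratified by region x mutation
# group x gene class (coding strata further split by classification)
expression_group_tests <- function(cat_rows, hotspot_sets, ez, wt, config) {
  res <- list()
  strata <- cat_rows[!is.na(gene_id)]
  if (nrow(strata) == 0) return(NULL)
  strata[, mut_group := ifelse(mut_type == "SNV", "SNV", "indel")]
  combos <- unique(strata[, .(region_class, mut_group, cgc_class)])
  for (ci in seq_len(nrow(combos))) {
    sub <- strata[region_class == combos$region_class[ci] &
                    mut_group == combos$mut_group[ci] &
                    cgc_class == combos$cgc_class[ci]]
    cls_splits <- if (combos$region_class[ci] == "protein_coding") {
      unique(hotspot_classification(sub, hotspot_sets))
    } else "all"
    for (cls in cls_splits) {
      gz <- c(); wz <- c()
      for (i in seq_len(nrow(sub))) {
        if (cls != "all") {
          hcls <- hotspot_classification(sub[i], hotspot_sets)
          if (hcls != cls) next
        }
        g <- sub$gene_id[i]
        if (!g %in% rownames(ez)) next
        hset <- hotspot_sets[[sub$mut_type[i]]]
        pats <- unique(hset$members[hotspot_id == sub$hotspot_id[i]]$patient)
        gz <- c(gz, ez[g, intersect(pats, colnames(ez))])
        wz <- c(wz, ez[g, intersect(wt[[g]] %||% character(), colnames(ez))])
      }
      tt <- group_expression_test(gz, wz, combos$cgc_class[ci])
      tt[, `:=`(region = combos$region_class[ci],
                mut_group = combos$mut_group[ci],
                cgc_class = combos$cgc_class[ci],
                classification = cls)]
      res[[length(res) + 1L]] <- tt
    }
  }
  out <- rbindlist(res)
  out[, q_value := bh_adjust(p_value)]
  out[]
}

# dominant member classification of each hotspot row
hotspot_classification <- function(rows, hotspot_sets) {
  vapply(seq_len(nrow(rows)), function(i) {
    hset <- hotspot_sets[[rows$mut_type[i]]]
    mem <- hset$members[hotspot_id == rows$hotspot_id[i]]
    if (!nrow(mem)) return("unknown")
    names(sort(table(mem$classification), decreasing = TRUE))[1]
  }, character(1))
}

# five-way grouping for the CAF permutation test: protein-coding hotspot
# members split by known-driver site and gene class; protein-coding
# singletons split by gene class
caf_permutation_groups <- function(mut_ann, cat_rows, hotspot_sets,
                                   genes = NULL) {
  lab <- rep(NA_character_, nrow(mut_ann))
  coding <- mut_ann$region_class == "protein_coding"
  cgc_genes <- if (!is.null(genes)) {
    genes$gene_id[genes$cgc_class != "non_cancer"]
  } else unique(cat_rows[cgc_class != "non_cancer"]$gene_id)
  mut_cgc <- coding & mut_ann$gene_id %in% cgc_genes
  driver_ids <- cat_rows[is_known_driver_site == TRUE &
                           region_class == "protein_coding"]$hotspot_id
  driver_members <- rbindlist(lapply(hotspot_sets, function(h)
    if (nrow(h$members)) h$members[hotspot_id %in% driver_ids,
                                   .(patient, chrom, start, mut_type)]
    else data.table()), use.names = TRUE)
  key <- paste(mut_ann$patient, mut_ann$chrom, mut_ann$start,
               mut_ann$mut_type)
  is_driver <- if (nrow(driver_members)) {
    key %in% paste(driver_members$patient, driver_members$chrom,
                   driver_members$start, driver_members$mut_type)
  } else rep(FALSE, nrow(mut_ann))
  hot <- mut_ann$in_hotspot
  lab[coding & hot & is_driver] <- "driver_hotspots"
  lab[coding & hot & !is_driver & mut_cgc] <- "cgc_hotspots"
  lab[coding & hot & !is_driver & !mut_cgc] <- "noncgc_hotspots"
  lab[coding & !hot & mut_cgc] <- "cgc_singletons"
  lab[coding & !hot & !mut_cgc] <- "noncgc_singletons"
  lab
}
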