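#!/usr/bin/env Rscript
# Compare observed hotspot multiplicity spectra against the null models:
# the uniform binomial model for SNVs and insertions, and the
# length-preserving deletion shuffle (500 iterations here; the method
# default is 10,000).

source("analysis/00_load_cohort.R")

inp <- load_cohort()
out_dir <- "results/null_models"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

muts <- dedupe_indels(normalize_indels(inp$mutations, inp$reference))
# slippage filter: homopolymer-bordering indel calls are artifacts and are
# excluded from the null comparison (the filter also applies to singletons)
indel <- muts$mut_type %in% c("INS", "DEL")
hp <- rep(FALSE, nrow(muts))
hp[indel] <- homopolymer_flag(muts[indel, .(chrom, start, end)],
                              inp$homopolymer_runs)
cat(sprintf("homopolymer-bordering indel calls excluded: %d\n", sum(hp)))
muts <- muts[!hp]
L <- sum(nchar(inp$reference))
N <- length(unique(muts$patient))

for (ty in c("SNV", "INS")) {
  det <- if (ty == "SNV") detect_snv_hotspots(muts) else
    detect_insertion_hotspots(muts)
  tab <- null_expectation_table(det$hotspots$multiplicity, L, N,
                                sum(muts$mut_type == ty))
  fwrite(tab, file.path(out_dir, paste0("null_", ty, ".tsv")), sep = "\t")
  top <- tab[observed > 0][which.max(k)]
  cat(sprintf(
    "%s: at multiplicity >= %d the uniform model expects %.3g sites, %d observed (FDR %.2g)\n",
    ty, top$k, top$expected, top$observed, top$fdr_expected_observed))
}

dels <- as.data.table(muts)[mut_type == "DEL",
                            .(patient, cohort, chrom, start, end)]
chrom_lengths <- nchar(inp$reference)
shuf <- shuffle_deletion_null(dels, chrom_lengths, n_iter = 500L, seed = 1L)
fwrite(shuf, file.path(out_dir, "null_DEL_shuffle.tsv"), sep = "\t")
cat(sprintf(
  "DEL: shuffle median expectation at multiplicity 2 is %.1f vs %d observed (p = %.3g)\n",
  shuf[k == 2]$expected_median, shuf[k == 2]$observed,
  shuf[k == 2]$p_value))
cat("null-model tables written to", out_dir, "\n")
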