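#!/usr/bin/env Rscript
# Detect SNV, insertion, and deletion hotspots and apply the artifact
# filters: indel left-normalization, same-patient duplicate removal,
# homopolymer-run removal for indel hotspots (annotation only for SNVs),
# and the site-specific noise filter on the top SNV hotspots.

source("analysis/00_load_cohort.R")

inp <- load_cohort()
out_dir <- "results/hotspots"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

muts <- normalize_indels(inp$mutations, inp$reference)
muts <- dedupe_indels(muts)
cat(sprintf("duplicate indel calls removed: %d\n", attr(muts, "n_removed")))

snv <- detect_snv_hotspots(muts)
ins <- detect_insertion_hotspots(muts)
del <- detect_deletion_hotspots(muts)
cat(sprintf("detected hotspots: %d SNV, %d insertion, %d deletion\n",
            nrow(snv$hotspots), nrow(ins$hotspots), nrow(del$hotspots)))

runs <- inp$homopolymer_runs
for (nm in c("ins", "del")) {
  res <- get(nm)
  flag <- homopolymer_flag(res$hotspots[, .(chrom, start, end)], runs)
  cat(sprintf("%s hotspots on homopolymer runs removed: %d of %d\n",
              toupper(nm), sum(flag), length(flag)))
  res$hotspots <- res$hotspots[!flag]
  assign(nm, res)
}
snv$hotspots[, homopolymer := homopolymer_flag(
  snv$hotspots[, .(chrom, start, end)], runs)]

nf <- apply_noise_filter(snv$hotspots, inp$noise_profile)
cat(sprintf("noise filter removed %d SNV hotspots (score > 20)\n",
            nrow(nf$removed)))
snv$hotspots <- nf$hotspots

fwrite(snv$hotspots, file.path(out_dir, "snv_hotspots.tsv"), sep = "\t")
fwrite(ins$hotspots, file.path(out_dir, "ins_hotspots.tsv"), sep = "\t")
fwrite(del$hotspots, file.path(out_dir, "del_hotspots.tsv"), sep = "\t")
cat("hotspot tables written to", out_dir, "\n")
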