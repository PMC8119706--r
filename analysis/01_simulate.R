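#!/usr/bin/env Rscript
# Generate the synthetic study cohort: a 10 Mb two-chromosome genome with
# 200 patients in 12 cohorts, background SNVs/indels, homopolymer slippage
# artifacts, duplicate indel calls, noisy recurrent sites, and the default
# panel of planted driver hotspots. All standard-format inputs plus the
# truth tables are written under results/cohort/.

library(hotspotscan)
library(data.table)

out_dir <- "results/cohort"
cfg <- sim_config(seed = 1L)
sim <- simulate_cohort(cfg, out_dir = out_dir)

fwrite(sim$truth$drivers, file.path(out_dir, "truth_drivers.tsv"), sep = "\t")
fwrite(sim$truth$slippage_hotspots,
       file.path(out_dir, "truth_slippage_hotspots.tsv"), sep = "\t")
fwrite(sim$truth$noisy_sites, file.path(out_dir, "truth_noisy_sites.tsv"),
       sep = "\t")
fwrite(sim$truth$homopolymer_runs,
       file.path(out_dir, "homopolymer_runs.tsv"), sep = "\t")

m <- as.data.table(sim$mutations)
cat(sprintf("cohort: %d patients / %d cohorts, %d mutations (%d SNV, %d DEL, %d INS)\n",
            cfg$n_patients, cfg$n_cohorts, nrow(m),
            sum(m$mut_type == "SNV"), sum(m$mut_type == "DEL"),
            sum(m$mut_type == "INS")))
cat(sprintf("planted: %d driver hotspots, %d slippage artifact hotspots, %d noisy sites, %d duplicate pairs\n",
            nrow(sim$truth$drivers), nrow(sim$truth$slippage_hotspots),
            nrow(sim$truth$noisy_sites), nrow(sim$truth$duplicates)))
cat("inputs written to", out_dir, "\n")
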