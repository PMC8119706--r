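# Shared loader for the analysis scripts: reads the standard-format cohort
# files written by 01_simulate.R back into the pipeline's input list.
# (Not numbered as a step; sourced by the later scripts.)

library(hotspotscan)
library(data.table)

load_cohort <- function(dir = "results/cohort") {
  stopifnot(file.exists(file.path(dir, "mutations.tsv")))
  muts <- read_mutations(file.path(dir, "mutations.tsv"), "tsv")
  ref <- Biostrings::readDNAStringSet(file.path(dir, "reference.fa"))
  reference <- setNames(as.character(ref), names(ref))
  pc <- read_purity_cn(file.path(dir, "purity.tsv"),
                       file.path(dir, "cn_segments.tsv"))
  cohorts <- setNames(muts$cohort, muts$patient)
  cohorts <- cohorts[!duplicated(names(cohorts))]
  list(
    mutations = muts,
    reference = reference,
    regions = read_regions_bed(file.path(dir, "regions.bed")),
    genes = read_gene_catalog(file.path(dir, "genes.tsv")),
    purity = pc$purity,
    cn_segments = pc$cn_segments,
    expression = read_expression_matrix(file.path(dir, "expression.tsv")),
    cohorts = cohorts,
    noise_profile = fread(file.path(dir, "noise_profile.tsv"),
                          colClasses = list(character = "chrom")),
    signature_profiles = fread(file.path(dir, "signatures.tsv"),
                               colClasses = list(character = "chrom")),
    driver_sites = fread(file.path(dir, "driver_sites.tsv"),
                         colClasses = list(character = "chrom")),
    homopolymer_runs = fread(file.path(dir, "homopolymer_runs.tsv"),
                             colClasses = list(character = "chrom")))
}
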