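Package: hotspotscan
Title: Site-Specific Somatic Mutation Hotspots Across Cancer Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects recurrently mutated genomic positions (SNV and insertion
    hotspots) and regions (deletion hotspots) across a cohort of whole cancer
    genomes, filters technical artifacts (duplicate indel calls, homopolymer
    slippage, site-specific sequencing noise), tests hotspot recurrence against
    uniform binomial, deletion-shuffle, and exact Poisson-binomial null models,
    assigns hotspots to functional regions through a priority hierarchy with
    nearest-TSS gene assignment, measures cancer-gene enrichment with
    Clopper-Pearson intervals, scores clonality via purity- and copy-number-
    corrected cancer allele fractions, tests expression aberrations against
    wild-type patients, attributes mutational-signature probabilities, and
    ranks hotspot driver evidence by Fisher's method. Ships a fully specified
    synthetic-cohort generator with a machine-readable truth set for
    calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    IRanges,
    S4Vectors,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
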