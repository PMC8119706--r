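---
title: "Detecting and scoring site-specific somatic hotspots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and scoring site-specific somatic hotspots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Across a cohort of whole cancer genomes, some genomic positions are mutated
in several patients. Most such recurrence is produced by heterogeneous
mutational processes and technical artifacts, but a small minority marks
positive selection — driver mutations, including non-coding ones such as
the well-known promoter hotspots of *TERT*. `hotspotscan` implements the
full analysis chain for this problem: detect recurrently mutated sites,
filter artifact classes, quantify how surprising the recurrence is under
background models, annotate each hotspot by functional region and
cancer-gene status, and score per-hotspot driver evidence from clonality,
expression, and mutational-signature data.

# Hotspot definitions and detection

A **hotspot** is type-specific:

* **SNV hotspot** — a single genomic position where two or more distinct
  patients carry an SNV; the nucleotide change may differ between
  patients.
* **Insertion hotspot** — an inter-base boundary where two or more
  distinct patients carry an insertion; insert sequence and length may
  differ.
* **Deletion hotspot** — a maximal cluster of deletions that pairwise
  overlap or lie immediately adjacent (single-linkage under the
  overlap-or-abut relation); a 1 bp gap separates clusters. The span is
  the union extent.

**Multiplicity** counts distinct patients, not calls: a patient
contributing two calls at one site adds 1. Internally all coordinates are
0-based half-open; every emitted table is 1-based inclusive.

Indels are left-normalized (shifted to their leftmost equivalent
representation) before anything else, so that caller-representation
differences become visible to the duplicate filter and deletion
clustering.

# Artifact filters

Three filters target known artifact classes; the indel filters also apply
to singleton indels used in the singleton-based comparisons.

1. **Duplicate indels.** Callers occasionally emit the same indel twice
   for one patient with a 1 bp representation shift or differing read
   counts. After normalization, two same-patient calls of the same type
   whose start and end each differ by at most 1 bp are treated as
   duplicates and *both* are removed. The tolerance of 1 bp is our
   operationalization of caller disagreements that are described only
   qualitatively in the literature.
2. **Homopolymer runs.** An indel that overlaps — or immediately flanks —
   a run of at least 9 identical reference bases is a likely
   replication-slippage artifact; such indel hotspots are removed. SNV
   hotspots bordering runs are only annotated, since the concern there is
   misclassification rather than a false site.
3. **Site-specific noise.** For the 1000 SNV hotspots with the most
   patients (ties at the boundary included), a noise score is computed
   from the percent `p(a, c)` of normal samples in cohort `c` with at
   least two reads supporting the non-reference nucleotide `a`:
   `score = sum_c log10(p(a, c) + 1)`. With several observed alternate
   alleles the maximum decides (a conservative choice among the
   defensible combination rules). Hotspots scoring above 20 are
   removed; hotspots without profile coverage are kept and flagged
   unscored.

# Null models

* **Uniform binomial.** Every patient mutates every site independently
  with `p = M / (N·L)` (`M` total mutations, `N` patients, `L` sites) — a
  deliberate simplification whose per-patient/per-site symmetry makes the
  per-multiplicity expected counts closed-form:
  `E[sites with >= k mutated patients] = L · P(Binomial(N, p) >= k)`.
  Tails are evaluated in log space so genome-scale expectations of order
  `1e-3` and below remain exact.
* **Deletion shuffle.** Deletions have extent, so their null keeps the
  observed number, lengths, and patient labels and re-places each deletion
  uniformly within its own chromosome, re-running the clustering; the
  per-multiplicity expectation is the median over iterations (default
  10,000) and the p-value is the proportion of iterations at or above the
  observed count.
* **Per-site Poisson-binomial.** When a position- and sample-specific
  probability matrix is available (from any external background
  mutation-rate model — fitting one is out of scope), the count of mutated
  patients at a site is Poisson-binomial; we evaluate its tail by exact
  iterative convolution, stable to a few thousand patients, and sum
  per-site tails into expected hotspot counts.

Two per-multiplicity false-discovery measures are reported, because more
than one defensible estimator exists: the ratio of expected to observed cumulative counts capped at 1
(equivalently, the Benjamini-Hochberg q-value of the shared per-site
binomial p-value at the class boundary) and a BH adjustment over per-class
Poisson tail p-values. Both lead to the same qualitative statement on our
cohorts: classes at multiplicity 2–3 are expected in bulk, classes beyond
the analytic threshold are not.

# Annotation

Functional regions form a fixed priority hierarchy — protein-coding,
protein-coding splice-site, 5' UTR, 3' UTR, promoter, non-coding
splice-site, enhancer — and a hotspot receives exactly the first class its
span overlaps (the two splice classes are merged in reports). Hotspots
overlapping nothing are intronic/intergenic and take the gene with the
nearest transcription start site in either direction; ties break to the
lower coordinate, then lexicographic gene id (a deterministic convention;
generic closest-interval tools leave ties implementation-defined). Optional
feature tracks (repeats, self-chains, palindrome loops, APOBEC3A sites,
dbSNP, conservation and ChIP-seq scores) attach flags and maximum
overlapping scores; a palindrome-loop flag is suppressed when the
homopolymer flag is set, since the loop annotation is then itself a run
artifact.

The transcription-factor screen is a direct position-weight-matrix
log-odds scan: score the ±5 bp reference and mutated windows over all
offsets and both strands with
`sum_i log2((p_i(base) + 1e-3) / background(base))` under a uniform
background, and report the delta (alt − ref). A positive delta flags
potential binding-site gain, negative loss. This deliberately replaces a
motif-database comparison tool: no significance calls are made, the delta
is an annotation for ranking and inspection only.

# Enrichment statistics

Region-wise hotspot (and singleton) densities are compared against the
intronic/intergenic baseline by a one-sided binomial upper tail with the
baseline per-bp rate as success probability and the region length as
opportunity count (evaluated as a Poisson tail for lengths beyond 1e7,
where the two are numerically identical). Cancer-gene enrichment per
cumulative group is the fold change of the group's cancer-gene proportion
over a baseline — either the overall proportion of Cancer Gene Census
genes among all genes, or the cancer-gene proportion among the region's
singletons — with the exact Clopper-Pearson 95% interval on the group
proportion divided by the (constant-treated) baseline. The second-hit
analysis asks whether regulatory hotspots carry same-patient missense
mutations in the same gene more often than regulatory singletons do, by a
two-sided Fisher's exact test; both the conditional-MLE odds ratio and the
plain ratio of proportions are reported, as the two estimators can
differ noticeably on strongly unbalanced tables.

# Clonality: CAF and delta-CAF

The cancer allele fraction corrects the variant allele fraction for tumor
purity `TP` and local copy number `CN`:

`CAF = VAF · (CN·TP + 2·(1 − TP)) / (CN·TP)`

Values may exceed 1 (multi-copy variants) and are not clipped. Because
copy-number loss inflates CAF over large regions, the working statistic is
**delta-CAF**: CAF minus the CAF of the nearest same-patient mutation at
least 2 kb away on the same chromosome and outside protein-coding gene
bodies (gene body, not merely CDS — our reading of "outside protein-coding
genes"). Delta-CAF values are z-normalized with the sample (n−1) standard
deviation. Positions falling in copy-number segment gaps default to CN 2
with a flag.

Group medians are tested by joint label permutation (default 100,000
iterations) across five protein-coding strata: known-driver hotspot
mutations, cancer-gene hotspots excluding drivers, other hotspots, and
cancer-gene/other singletons, with singletons downsampled once to 10%
before permuting. The p-value is the proportion of null medians at or
above the observed; an add-one variant avoids zero p-values. The "high"
and "above-median" per-hotspot flags derive from the 90th percentile and
median of the cancer-gene protein-coding hotspot z distribution — computed
from the data at hand, never fixed constants, since they are properties
of the cohort being analyzed.

# Expression

Expression values are z-normalized within each (gene, cohort) cell so
cohorts are comparable. A gene's **wild-type set** contains patients with
no copy-number change over the gene body and no SNV/indel in its coding or
regulatory intervals (splice-sites, promoters, UTRs). Enhancer mutations
do not disqualify — regulatory disqualification is limited to promoter/UTR/splice
elements by default — but a
configuration toggle tightens this for sensitivity analyses. Group and
per-hotspot comparisons use the Wilcoxon rank-sum test with
class-dependent sidedness: greater for oncogenes, less for tumor
suppressors, two-sided otherwise; coding strata are further split by
variant classification (missense/nonsense, frameshift/in-frame). Exact
enumeration is used for small untied samples (m+n ≤ 50), the normal
approximation with continuity correction otherwise; fully tied samples
yield p = 1.

# Ranking

Each catalog hotspot receives up to two one-sided p-values: delta-CAF z of
its members against singletons in the same region of the same gene
(alternative: hotspot greater), and expression z of its mutated patients
against the gene's wild-type set (sidedness by gene class). Fisher's
method combines them (`-2·sum(ln p)` against chi-squared with `2k` df);
with one defined p-value the combination equals it; with none the hotspot
sinks below all scored rows and orders by multiplicity. The rank score is
`-log2(combined p)` with p floored at 1e-300; combined p-values are
deliberately not multiple-testing corrected — they rank, they do not call
significance.

# The synthetic cohort generator

The generator is first-class, tested code that defines the study
conditions for calibration and parameter-recovery experiments. Defaults:

* **Genome**: two chromosomes, 6 + 4 Mb, i.i.d. uniform base composition,
  with 300 planted homopolymer runs of 9–15 bp at recorded positions
  (i.i.d. sequence also yields a few dozen natural runs of 9+; both are
  truth via the run table).
* **Cohort**: 200 patients in 12 cohorts. Twelve cohorts — rather than the
  minimum two — keep the noise score meaningful: each cohort contributes
  at most `log10(101) ≈ 2.0`, so a removal threshold of 20 is reachable
  only with about ten or more affected cohorts, as in the multi-cohort
  setting the filter was designed for.
* **Mutation load**: 100,000 SNVs, 20,000 deletions, 10,000 insertions,
  placed uniformly (per-region relative rates are configurable but default
  to 1 so that the driver-free cohort matches the uniform binomial null
  exactly; a trinucleotide-bias multiplier is available and off by
  default). This per-bp rate is deliberately higher than genome-wide
  cancer averages: it compresses the multiplicity statistics of a 3 Gb
  cohort into a 10 Mb toy so that multiplicity-2 hotspots appear in the
  hundreds and the analytic threshold sits at multiplicity 4.
* **Genes**: one gene every 60 kb (~167 genes), each with promoter
  (1 kb), 5' UTR, splice-sites, coding region (1.5 kb), 3' UTR and a distal
  enhancer, all disjoint; ~7% of genes are cancer genes cycling through
  oncogene / tumor suppressor / other.
* **Artifacts**: 15% of indels relocated onto homopolymer runs
  (slippage enrichment), 30 explicit recurrent slippage deletion hotspots,
  20 same-patient duplicate indel pairs shifted by 1 bp, and 8 noisy
  recurrent SNV sites whose noise-profile rows are drawn at 70–100% across
  all cohorts (score ≥ 12·log10(71) ≈ 22 > 20, so removal is guaranteed by
  construction).
* **Clonality and reads**: passenger cancer-cell fractions are
  Uniform(0.4, 0.7) and drivers add +0.3, so driver VAFs never clip at 1;
  VAF is realized by binomial read sampling at 60x; purity is
  Uniform(0.3, 0.95); each patient has a Poisson(3) number of 200 kb
  copy-number events with CN in {1, 3, 4}.
* **Drivers**: the default panel plants seven hotspots (coding missense in
  an oncogene, coding nonsense in a tumor suppressor, promoter, 5' UTR,
  enhancer, splice-site, and a coding frameshift deletion) at
  multiplicities 4–8, each with a +0.3 CAF shift and a 1-sd expression
  effect signed by gene class (down for tumor suppressors).
* **Signatures**: two synthetic processes mixed per cohort with mild
  per-mutation jitter.

Everything is reproducible from one integer seed, and a truth set records
planted coordinates, patients, generative clonalities, artifact positions
and duplicate pairs.

What the generator does *not* emulate: real trinucleotide context
preferences, chromatin covariates of mutation rate, cancer-type
composition, subclonal population structure, or caller-specific error
modes beyond the three artifact classes above. Passing calibration and
recovery tests therefore demonstrates the statistical machinery is
correct and well-calibrated under its own assumptions — not that those
assumptions capture everything in real cohorts.

# Numerical choices and problem sizes

* Binomial/Poisson tails in log space; the Poisson-binomial convolution is
  exact (no truncation) and `O(N^2)`.
* The deletion-shuffle and permutation tests keep the method defaults
  (10,000 iterations; 100,000 permutations) in their signatures; the
  analysis scripts and acceptance runs use 500–5,000 iterations, the
  problem sizes we chose for desk-scale replication, and fixed seeds make
  every run bit-reproducible.
* Calibration experiments use 20 driver-free cohorts at the default
  conditions; recovery experiments 20 cohorts with the default driver
  panel (12 in the acceptance script).
* Wilcoxon tests switch from exact enumeration to the corrected normal
  approximation at m+n > 50 or in the presence of ties.
* Degenerate inputs: zero-spread z-scores are undefined with a warning;
  empty singleton strata or missing expression engage the documented
  single-p and multiplicity-only ranking fallbacks; a zero-rate baseline
  region flags fold changes as undefined rather than erroring.

# Known limitations

* The uniform binomial model is intentionally naive; on real cohorts it
  understates clustering from mutational processes, which is exactly why
  the per-site Poisson-binomial route accepts an external probability
  matrix.
* The PWM delta screen reports effect sizes without significance; motif
  hits should be inspected, not counted as discoveries.
* The duplicate-indel tolerance (1 bp) and the noise-score combination
  rule (maximum over alts) are our operationalizations of qualitatively
  described filters.
* Deletion hotspot spans merge chains of overlapping deletions, so a span
  can exceed any individual member; region assignment uses the
  highest-priority class touched by the span.
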