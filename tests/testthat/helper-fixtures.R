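# shared fixture builders; everything is generated in code

library(data.table)

# mutation rows with minimal ceremony
mk_muts <- function(patient, chrom, start, mut_type = "SNV",
                    end = NULL, ref = "A", alt = "T",
                    cohort = "c1", vaf = NA_real_,
                    classification = "unknown") {
  n <- max(length(patient), length(start))
  patient <- rep_len(patient, n); chrom <- rep_len(chrom, n)
  start <- rep_len(start, n); mut_type <- rep_len(mut_type, n)
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  if (is.null(end)) {
    end <- ifelse(mut_type == "SNV", start + 1L,
                  ifelse(mut_type == "INS", start, start + 1L))
  }
  as_mutation_table(data.table(
    patient = patient, cohort = rep_len(cohort, n), chrom = chrom,
    start = as.integer(start), end = as.integer(end),
    mut_type = mut_type, ref = ref, alt = alt,
    vaf = rep_len(vaf, n),
    classification = rep_len(classification, n)))
}

# brute-force connected components under overlap-or-adjacent (gap 0)
brute_deletion_clusters <- function(start, end) {
  n <- length(start)
  adj <- outer(seq_len(n), seq_len(n), function(i, j) {
    start[i] <= end[j] & start[j] <= end[i]  # overlap or abut (half-open)
  })
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        m <- min(comp[i], comp[j]); comp[i] <- m; comp[j] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# exact Poisson-binomial tail by full outcome enumeration (N <= 15)
enumerate_poisbin_tail <- function(probs, k) {
  n <- length(probs)
  total <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    if (sum(bits) >= k) {
      total <- total + prod(ifelse(bits == 1, probs, 1 - probs))
    }
  }
  total
}

# tiny reference as named character vector
mk_reference <- function(...) {
  x <- c(...)
  vapply(x, toupper, character(1))
}

# small gene catalog
mk_genes <- function(gene_id, chrom, tss, cgc_class = "non_cancer") {
  n <- length(gene_id)
  g <- data.table(gene_id = gene_id, chrom = rep_len(chrom, n),
                  tss = as.integer(tss), strand = "+",
                  cgc_class = rep_len(cgc_class, n))
  setattr(g, "n_genes_total", n)
  setattr(g, "n_cgc_total", sum(g$cgc_class != "non_cancer"))
  g
}
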