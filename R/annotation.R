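#' Assign hotspots to functional regions via the priority hierarchy
#'
#' Each hotspot is allowed to overlap exactly one element type: the first
#' class in [region_hierarchy()] whose interval overlaps the hotspot span
#' wins, and the gene comes from that interval. Hotspots overlapping no
#' element are intronic/intergenic and are assigned to the gene with the
#' nearest transcription start site. In the output, protein-coding and
#' non-coding splice-sites are merged into `splice_site`.
#'
#' @param hotspots `data.table` with `chrom, start, end, mut_type` (0-based
#'   half-open; insertion spans are zero-length boundaries).
#' @param regions Region table from [read_regions_bed()] (or same layout).
#' @param genes Gene catalog (for the nearest-TSS fallback).
#' @return The hotspot table with `region_class`, `gene_id`,
#'   `gene_distance` (bp, 0 for direct overlap) columns added.
#' @export
assign_region <- function(hotspots, regions, genes) {
  hs <- copy(as.data.table(hotspots))
  hs[, `:=`(region_class = "intronic_intergenic", gene_id = NA_character_,
            gene_distance = NA_real_)]
  if (nrow(hs) == 0) return(hs[])
  regions <- as.data.table(regions)
  hier <- region_hierarchy()
  if (nrow(regions)) {
    regions <- regions[region_class %in% hier]
    regions[, prio := match(region_class, hier)]
    for (chr in unique(hs$chrom)) {
      hi <- which(hs$chrom == chr)
      rr <- regions[chrom == chr]
      if (nrow(rr) == 0) next
      # widen zero-length insertion anchors to the two flanking bases
      qs <- hs$start[hi]; qe <- hs$end[hi]
      zero <- qe == qs
      q <- IRanges::IRanges(start = qs + 1L - as.integer(zero), end = pmax(qe, qs + 1L))
      s <- IRanges::IRanges(start = rr$start + 1L, end = rr$end)
      ov <- IRanges::findOverlaps(q, s)
      if (length(ov) == 0) next
      ovdt <- data.table(h = S4Vectors::queryHits(ov),
                         prio = rr$prio[S4Vectors::subjectHits(ov)],
                         gene = rr$gene_id[S4Vectors::subjectHits(ov)])
      best <- unique(ovdt[order(h, prio)], by = "h")
      hs$region_class[hi[best$h]] <- hier[best$prio]
      hs$gene_id[hi[best$h]] <- best$gene
      hs$gene_distance[hi[best$h]] <- 0
    }
  }
  # nearest-TSS fallback for intronic/intergenic
  need <- which(hs$region_class == "intronic_intergenic")
  if (length(need) && !is.null(genes) && nrow(genes)) {
    nt <- nearest_tss(hs$chrom[need], hs$start[need] + 1L, genes)
    hs$gene_id[need] <- nt$gene_id
    hs$gene_distance[need] <- nt$distance
  }
  hs[region_class %in% c("protein_splice_site", "noncoding_splice_site"),
     region_class := "splice_site"]
  hs[]
}

#' Nearest transcription start site on a chromosome
#'
#' Minimum absolute distance to any TSS on either strand; ties are broken
#' by lower genomic coordinate, then lexicographic gene id.
#'
#' @param chrom,pos_1based Vectors of query positions (1-based).
#' @param genes Gene catalog with `gene_id, chrom, tss`.
#' @return `data.table(gene_id, distance)`; `NA` when the chromosome has no
#'   gene (with a warning).
#' @export
nearest_tss <- function(chrom, pos_1based, genes) {
  genes <- as.data.table(genes)
  gene_out <- rep(NA_character_, length(chrom))
  dist_out <- rep(NA_real_, length(chrom))
  warned <- FALSE
  for (chr in unique(chrom)) {
    qi <- which(chrom == chr)
    gg <- genes[genes$chrom == chr]
    if (nrow(gg) == 0) {
      if (!warned) { warning("no gene on chromosome ", chr); warned <- TRUE }
      next
    }
    gg <- gg[order(tss, gene_id)]
    # identical TSS positions: keep the lexicographically first gene
    gg <- unique(gg, by = "tss")
    p <- pos_1based[qi]
    li <- findInterval(p, gg$tss)          # rightmost TSS <= p
    ri <- pmin(li + 1L, nrow(gg))          # leftmost TSS > p
    lofs <- pmax(li, 1L)
    dl <- ifelse(li >= 1L, p - gg$tss[lofs], Inf)
    dr <- ifelse(li < nrow(gg), gg$tss[ri] - p, Inf)
    # tie -> lower coordinate, i.e. the left candidate
    pick <- ifelse(dl <= dr, lofs, ri)
    gene_out[qi] <- gg$gene_id[pick]
    dist_out[qi] <- pmin(dl, dr)
  }
  data.table(gene_id = gene_out, distance = dist_out)
}

#' Cancer-gene class and known-driver-site flag
#'
#' @param hotspots Annotated hotspot table (needs `gene_id, chrom, start`).
#' @param genes Gene catalog with `cgc_class`.
#' @param driver_positions Optional `data.table(chrom, pos_1based)` of known
#'   somatic driver positions; a hotspot at a listed position (1-based start
#'   for SNVs/deletions, boundary base for insertions) is flagged.
#' @return Hotspot table with `cgc_class` and `is_known_driver_site` added.
#' @export
classify_gene <- function(hotspots, genes, driver_positions = NULL) {
  hs <- copy(as.data.table(hotspots))
  genes <- as.data.table(genes)
  lut <- setNames(genes$cgc_class, genes$gene_id)
  hs[, cgc_class := unname(lut[gene_id])]
  if (any(is.na(hs$cgc_class) & !is.na(hs$gene_id))) {
    warning("gene(s) absent from catalog treated as non_cancer")
  }
  hs[is.na(cgc_class), cgc_class := "non_cancer"]
  hs[, is_known_driver_site := FALSE]
  if (!is.null(driver_positions) && nrow(driver_positions)) {
    dp <- as.data.table(driver_positions)
    key <- paste(dp$chrom, dp$pos_1based)
    hs[, is_known_driver_site := paste(chrom, start + 1L) %in% key]
  }
  hs[]
}

#' Attach genomic feature flags and scores to hotspots
#'
#' Boolean overlap flags for interval tracks (repeats, self-chains,
#' palindrome loops, APOBEC3A sites, dbSNP) and the maximum overlapping
#' score for score tracks (conservation, ChIP-seq). When a hotspot carries
#' the homopolymer flag, an overlapping palindrome-loop annotation is
#' treated as a homopolymer artifact and suppressed.
#'
#' @param hotspots Hotspot table (needs `chrom, start, end`; a logical
#'   `homopolymer` column is honored if present).
#' @param tracks Named list; each element a `data.table(chrom, start, end)`
#'   (0-based half-open), optionally with a `score` column. Elements with a
#'   score column yield `<name>_score` (max overlapping score, NA when no
#'   overlap); others yield a logical `<name>` column.
#' @return Hotspot table with flag/score columns added.
#' @export
annotate_features <- function(hotspots, tracks = list()) {
  hs <- copy(as.data.table(hotspots))
  if (!length(tracks) || nrow(hs) == 0) return(hs[])
  for (nm in names(tracks)) {
    tr <- as.data.table(tracks[[nm]])
    has_score <- "score" %in% names(tr)
    col <- if (has_score) paste0(nm, "_score") else nm
    if (has_score) hs[, (col) := NA_real_] else hs[, (col) := FALSE]
    if (nrow(tr) == 0) next
    for (chr in unique(hs$chrom)) {
      hi <- which(hs$chrom == chr)
      rr <- tr[chrom == chr]
      if (nrow(rr) == 0) next
      qs <- hs$start[hi]; qe <- pmax(hs$end[hi], hs$start[hi] + 1L)
      q <- IRanges::IRanges(start = qs + 1L, end = qe)
      s <- IRanges::IRanges(start = rr$start + 1L, end = rr$end)
      ov <- IRanges::findOverlaps(q, s)
      if (length(ov) == 0) next
      if (has_score) {
        agg <- data.table(h = S4Vectors::queryHits(ov),
                          sc = rr$score[S4Vectors::subjectHits(ov)])
        mx <- agg[, .(sc = max(sc)), by = h]
        set(hs, i = hi[mx$h], j = col, value = mx$sc)
      } else {
        set(hs, i = hi[unique(S4Vectors::queryHits(ov))], j = col, value = TRUE)
      }
    }
  }
  if ("palindrome_loop" %in% names(hs) && "homopolymer" %in% names(hs)) {
    hs[homopolymer == TRUE, palindrome_loop := FALSE]
  }
  hs[]
}

#' Read a MEME-like position weight matrix file
#'
#' Minimal plain-text reader for probability matrices in MEME motif format:
#' a `MOTIF <id>` line followed by a `letter-probability matrix` header and
#' one row of A/C/G/T probabilities per motif position. Several motifs per
#' file are supported.
#'
#' @param path File path.
#' @return Named list of motifs; each a list with `motif_id` and `matrix`
#'   (positions x 4, columns A,C,G,T).
#' @export
read_pwm_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "MOTIF")) {
      motif_id <- strsplit(ln, "\\s+")[[1]][2]
      i <- i + 1L
      while (i <= length(lines) &&
             !grepl("letter-probability matrix", lines[i])) i <- i + 1L
      i <- i + 1L
      rows <- list()
      while (i <= length(lines)) {
        vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]),
                                                     "\\s+")[[1]]))
        if (length(vals) != 4 || any(is.na(vals))) break
        rows[[length(rows) + 1L]] <- vals
        i <- i + 1L
      }
      m <- do.call(rbind, rows)
      colnames(m) <- c("A", "C", "G", "T")
      out[[motif_id]] <- list(motif_id = motif_id, matrix = m)
    } else i <- i + 1L
  }
  out
}

#' PWM gain/loss delta score for a variant
#'
#' Scores the reference and mutated sequence windows (+/-5 bp around the
#' variant) against a position weight matrix. The window score is the
#' maximum log2 odds over all offsets and both strands:
#' `sum_i log2((pwm[i, base] + pseudocount) / background[base])`. A positive
#' delta (`best_alt - best_ref`) flags a potential binding-site gain, a
#' negative delta a potential loss. The delta is reported for annotation
#' and ranking only, not as a significance call.
#'
#' @param ref_window,alt_window Character strings (the alt window is the
#'   edited sequence; for indels it is re-centered on the edit).
#' @param pwm A motif from [read_pwm_meme()] or a bare positions x 4 matrix.
#' @param pseudocount Added to each probability (default 1e-3).
#' @param background Named base probabilities (default uniform).
#' @return List `best_ref`, `best_alt`, `delta`.
#' @export
pwm_delta_score <- function(ref_window, alt_window, pwm,
                            pseudocount = 1e-3,
                            background = c(A = .25, C = .25, G = .25, T = .25)) {
  m <- if (is.list(pwm)) pwm$matrix else pwm
  br <- pwm_best_score(ref_window, m, pseudocount, background)
  ba <- pwm_best_score(alt_window, m, pseudocount, background)
  list(best_ref = br, best_alt = ba, delta = ba - br)
}

pwm_best_score <- function(window, m, pseudocount, background) {
  window <- toupper(window)
  w <- nchar(window); k <- nrow(m)
  scan1 <- function(seqchars) {
    n <- length(seqchars)
    if (n < k) return(-Inf)
    best <- -Inf
    for (off in 0:(n - k)) {
      s <- 0
      ok <- TRUE
      for (i in seq_len(k)) {
        b <- seqchars[off + i]
        if (!b %in% colnames(m)) { ok <- FALSE; break }
        s <- s + log2((m[i, b] + pseudocount) / background[[b]])
      }
      if (ok && s > best) best <- s
    }
    best
  }
  fwd <- strsplit(window, "")[[1]]
  rev <- rev(chartr("ACGT", "TGCA", fwd))
  max(scan1(fwd), scan1(rev))
}

#' Reverse complement of a DNA string
#' @param x Character string.
#' @return Reverse complement string.
#' @export
revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1]]),
        collapse = "")
}
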