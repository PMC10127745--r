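# Independent oracles and small fixtures used across the suite.

# Scaled-down simulation config for fast unit tests; study-scale defaults are
# exercised in test-acceptance.R.
small_cfg <- function(seed = 1L, ...) {
  sim_config(seed = seed,
             n_taxa = 12L,
             genes = c(nad1 = 160L, nad3 = 120L, cox1 = 200L, atp9 = 75L,
                       cob = 250L, cox2 = 150L),
             panel_only_genes = c(nad9 = 120L),
             intergenic_len = 200L,
             repeat_spec = list(unit_len = 50L, copies = 4L,
                                max_mismatch = 2L),
             n_background = 2L,
             background_len = 3000L,
             ...)
}

str_dist <- function(a, b) sum(charToRaw(a) != charToRaw(b))

panel_consensus_prot <- function(g) panel_consensus(g$taxa)

random_spacer <- function(n, gc = 0.25) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Naive six-frame ORF enumeration: walks every frame codon by codon,
# independent of the rle-based implementation.
orf_oracle <- function(seq, code, min_aa) {
  n <- nchar(seq)
  stops <- names(code$table)[code$table == "*"]
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (off in 0:2) {
      run_start <- NULL
      ncod <- (n - off) %/% 3
      k <- 0
      for (i in seq_len(ncod)) {
        codon <- substr(s, off + 3 * i - 2, off + 3 * i)
        if (codon %in% stops) {
          if (!is.null(run_start) && k >= min_aa)
            out[[length(out) + 1]] <- c(run_start, i - 1, off,
                                        strand == "-")
          run_start <- NULL
          k <- 0
        } else {
          if (is.null(run_start)) run_start <- i
          k <- k + 1
        }
      }
      if (!is.null(run_start) && k >= min_aa)
        out[[length(out) + 1]] <- c(run_start, ncod, off, strand == "-")
    }
  }
  rows <- lapply(out, function(x) {
    a <- x[3] + (x[1] - 1) * 3     # 0-based on translated strand
    b <- x[3] + x[2] * 3
    if (x[4]) { tmp <- a; a <- n - b; b <- n - tmp }
    data.frame(start = a, end = b, frame = x[3],
               strand = if (x[4]) "-" else "+", n_aa = x[2] - x[1] + 1)
  })
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(start = integer(0), end = integer(0),
                        frame = integer(0), strand = character(0),
                        n_aa = integer(0))
  df <- df[order(df$start, df$end, df$strand, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Brute-force recount of the stop-codon tally straight from CDS strings and
# alignments, sharing no code with map_stop_sites/tally_stop_sites.
tally_oracle <- function(cds_set, msas) {
  codons3 <- c("TGA", "TAG", "TAA")
  total <- counted <- excluded <- setNames(rep(0L, 3), codons3)
  aa_counts <- list(TGA = c(), TAG = c(), TAA = c())
  for (id in names(cds_set)) {
    seq <- cds_set[[id]]$seq
    msa <- msas[[id]]
    ncod <- nchar(seq) %/% 3
    for (k in seq_len(ncod)) {
      cd <- substr(seq, 3 * k - 2, 3 * k)
      if (!(cd %in% codons3) || grepl("N", cd)) next
      if (k == ncod) next                      # terminal terminator
      total[cd] <- total[cd] + 1L
      col <- msa$col_of_codon[k]
      colres <- msa$panel[, col]
      nong <- colres[colres != "-"]
      occ <- length(nong) / length(colres)
      if ((1 - occ) > 0.5 || occ < 0.5) { excluded[cd] <- excluded[cd] + 1L; next }
      best <- NA; bestn <- 0; tie <- FALSE
      for (r in unique(nong)) {
        nr <- sum(nong == r)
        if (nr > bestn) { best <- r; bestn <- nr; tie <- FALSE }
        else if (nr == bestn) tie <- TRUE
      }
      if (tie || bestn / length(nong) <= 0.5) {
        excluded[cd] <- excluded[cd] + 1L
      } else {
        counted[cd] <- counted[cd] + 1L
        aa_counts[[cd]] <- c(aa_counts[[cd]], best)
      }
    }
  }
  list(total = total, counted = counted, excluded = excluded,
       aa_counts = lapply(aa_counts, function(v) table(factor(v))))
}

# Alignment-free k-mer coverage estimate: fraction of read bases whose
# 31-mers occur in the contig (either strand), scaled to depth.
kmer_coverage <- function(contig, reads, k = 31) {
  both <- paste0(contig, "N", revcomp(contig))
  pos <- seq_len(nchar(both) - k + 1)
  ref_kmers <- unique(substring(both, pos, pos + k - 1))
  hit_bases <- 0
  for (r in reads) {
    if (nchar(r) < k) next
    rp <- seq_len(nchar(r) - k + 1)
    rk <- substring(r, rp, rp + k - 1)
    if (mean(rk %in% ref_kmers) > 0.5) hit_bases <- hit_bases + nchar(r)
  }
  hit_bases / nchar(contig)
}

# Exhaustive approximate-repeat scan: every pair of windows of length ulen
# compared by Hamming distance (tiny sequences only).
repeat_scan_oracle <- function(seq, ulen, max_mm) {
  n <- nchar(seq)
  if (n < 2 * ulen) return(list())
  starts <- seq_len(n - ulen + 1)
  wins <- substring(seq, starts, starts + ulen - 1)
  pairs <- list()
  for (i in seq_along(starts)) for (j in seq_along(starts)) {
    if (starts[j] < starts[i] + ulen) next
    mm <- sum(charToRaw(wins[i]) != charToRaw(wins[j]))
    if (mm <= max_mm) pairs[[length(pairs) + 1]] <- c(starts[i], starts[j], mm)
  }
  pairs
}
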