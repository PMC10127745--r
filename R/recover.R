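# Mitochondrial genome recovery: per-contig coverage/GC statistics, homology
# seeding, blob-style classification, and the iterative bait-and-extend read
# mapper (minimum overlap, maximum mismatch fraction, no gaps; repeated until
# no further reads can be mapped).

# ---- ungapped read matching -------------------------------------------------
# Reads are anchored to the reference by exact k-mer seeds spaced every
# floor(k/2) positions, so any mismatch-free stretch of >= 2k-1 nt in the
# overlapping region guarantees an anchor; candidate placements are then
# verified by exact mismatch counting over the clipped overlap window.

MATCH_K <- 24L

# Reverse complement of many sequences at once.
revcomp_many <- function(seqs) {
  if (!length(seqs)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

# Seed table for a read set: one row per (read, orientation, offset) seed
# k-mer, for both orientations of every read.
build_seed_table <- function(fwd, rc, k = MATCH_K) {
  step <- max(1L, k %/% 2L)
  one <- function(seqs, rcflag) {
    lens <- nchar(seqs)
    rows <- lapply(seq_along(seqs), function(i) {
      n <- lens[i]
      if (n < k) return(NULL)
      offs <- unique(c(seq(1L, n - k + 1L, by = step), n - k + 1L))
      data.frame(read = i, rcflag = rcflag, off = offs,
                 kmer = substring(seqs[i], offs, offs + k - 1L),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  rbind(one(fwd, 0L), one(rc, 1L))
}

consensus_kmer_index <- function(consensus, k = MATCH_K) {
  L <- nchar(consensus)
  if (L < k) return(NULL)
  pos <- seq_len(L - k + 1L)
  kmers <- substring(consensus, pos, pos + k - 1L)
  ukmers <- unique(kmers)
  list(ukmers = ukmers, pos_by_kmer = split(pos, match(kmers, ukmers)))
}

# Best ungapped placement per read on a consensus, computed for all reads
# whose index appears in `live`. Seeds of all live reads are matched against
# the consensus k-mer index in one batch; candidate diagonals are then
# verified by exact mismatch counting over the clipped overlap window.
# diag is the 1-based consensus coordinate of read position 1 (can fall
# outside [1, L] for overhanging placements). Returns a data.frame
# (read, rcflag, diag, overlap, mismatches), one row per recruited read.
ungapped_best_hits <- function(consensus, fwd, rc, seed_tab, live,
                               min_overlap, max_mismatch_frac) {
  empty <- data.frame(read = integer(0), rcflag = integer(0),
                      diag = integer(0), overlap = integer(0),
                      mismatches = integer(0))
  idx <- consensus_kmer_index(consensus)
  if (is.null(idx) || is.null(seed_tab)) return(empty)
  L <- nchar(consensus)
  rows <- seed_tab[seed_tab$read %in% live, , drop = FALSE]
  if (!nrow(rows)) return(empty)
  m <- match(rows$kmer, idx$ukmers)
  keep <- which(!is.na(m))
  if (!length(keep)) return(empty)
  plist <- idx$pos_by_kmer[m[keep]]
  nlen <- lengths(plist)
  cand <- data.frame(
    read = rep.int(rows$read[keep], nlen),
    rcflag = rep.int(rows$rcflag[keep], nlen),
    diag = unlist(plist, use.names = FALSE) - rep.int(rows$off[keep], nlen) + 1L)
  key <- (cand$read * 2 + cand$rcflag) * 4e6 + (cand$diag + 2e6)
  cand <- cand[!duplicated(key), , drop = FALSE]
  cand <- cand[order(cand$read, cand$rcflag, cand$diag), , drop = FALSE]

  best <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(cand))) {
    rd <- cand$read[i]
    s <- if (cand$rcflag[i] == 1L) rc[rd] else fwd[rd]
    rl <- nchar(s)
    d <- cand$diag[i]
    cs <- max(1L, d)
    ce <- min(L, d + rl - 1L)
    ov <- ce - cs + 1L
    if (ov < min_overlap) next
    rs <- cs - d + 1L
    mm <- str_mismatches(substr(s, rs, rs + ov - 1L),
                         substr(consensus, cs, ce))
    if (mm / ov > max_mismatch_frac) next
    kk <- as.character(rd)
    b <- best[[kk]]
    if (is.null(b) || ov > b$overlap ||
        (ov == b$overlap && mm < b$mismatches))
      best[[kk]] <- list(rcflag = cand$rcflag[i], diag = d,
                         overlap = ov, mismatches = mm)
  }
  hits <- ls(best)
  if (!length(hits)) return(empty)
  out <- do.call(rbind, lapply(hits, function(kk) {
    b <- best[[kk]]
    data.frame(read = as.integer(kk), rcflag = b$rcflag, diag = b$diag,
               overlap = b$overlap, mismatches = b$mismatches)
  }))
  out[order(out$read), , drop = FALSE]
}

#' Per-contig coverage and GC statistics
#'
#' Maps every read (either orientation) against every contig with the
#' package's ungapped matcher and reports mean depth and GC fraction per
#' contig. A read mapping to several contigs contributes its overlap
#' fractionally (1/n) to each, so repeated sequence does not inflate depth.
#'
#' @param contigs named character vector of contig sequences.
#' @param reads character vector of reads (orientation arbitrary).
#' @param min_overlap minimum overlap (nt) for a read to count as mapped.
#' @param max_mismatch_frac maximum mismatches/overlap.
#' @return data.frame with contig_id, length, coverage, gc.
#' @export
contig_stats <- function(contigs, reads, min_overlap = 100L,
                         max_mismatch_frac = 0.01) {
  stopifnot(length(contigs) > 0)
  ids <- names(contigs) %||% sprintf("contig%d", seq_along(contigs))
  fwd <- unname(reads)
  rc <- revcomp_many(fwd)
  seed_tab <- build_seed_table(fwd, rc)
  ov <- matrix(0, nrow = length(reads), ncol = length(contigs))
  for (j in seq_along(contigs)) {
    hits <- ungapped_best_hits(contigs[[j]], fwd, rc, seed_tab,
                               live = seq_along(fwd),
                               min_overlap, max_mismatch_frac)
    ov[hits$read, j] <- hits$overlap
  }
  nhits <- rowSums(ov > 0)
  frac <- ov / pmax(nhits, 1L)
  data.frame(contig_id = ids,
             length = vapply(contigs, nchar, integer(1), USE.NAMES = FALSE),
             coverage = colSums(frac) / vapply(contigs, nchar, integer(1),
                                               USE.NAMES = FALSE),
             gc = vapply(contigs, gc_content, numeric(1), USE.NAMES = FALSE),
             row.names = NULL)
}

#' Majority-consensus protein of an aligned panel gene
#'
#' Per-column majority over the panel rows, ignoring gaps; ties break toward
#' the lexicographically smallest residue.
#'
#' @param taxa character vector of mutually aligned proteins.
#' @return consensus protein string.
#' @export
panel_consensus <- function(taxa) {
  mat <- do.call(rbind, strsplit(unname(taxa), "", fixed = TRUE))
  paste(apply(mat, 2L, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return("-")
    tt <- table(col)
    names(tt)[which.max(tt)]      # which.max: first of ties, names sorted
  }), collapse = "")
}

#' Seed mitochondrial contigs by translated protein homology
#'
#' A contig is a seed if any of its six reading frames aligns locally against
#' a gene's panel consensus protein with score at or above `min_score`.
#'
#' @param contigs named character vector.
#' @param panel an `ortho_panel` or named list with per-gene `taxa` vectors.
#' @param code genetic code used for the six-frame translation (stops are
#'   rendered as X so alignments can cross them).
#' @param min_score minimum Smith-Waterman score (BLOSUM62, gap open 11,
#'   extend 1); the default clears the composition-biased null of AT-rich
#'   frame translations.
#' @return data.frame of hits (contig_id, gene, score, strand, frame, start,
#'   end — nucleotide, 0-based half-open); seed ids in `attr(,"seeds")`.
#' @export
seed_mito_contigs <- function(contigs, panel, code = genetic_code("table4"),
                              min_score = 100) {
  hits <- list()
  refs <- lapply(panel, function(g) panel_consensus(g$taxa %||% g))
  for (cid in names(contigs)) {
    frames <- six_frames(contigs[[cid]], code)
    n <- nchar(contigs[[cid]])
    for (fr in frames) {
      if (nchar(fr$protein) < 10L) next
      subj <- Biostrings::AAString(fr$protein)
      for (g in names(refs)) {
        al <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(refs[[g]]), subj, type = "local",
          substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
        sc <- Biostrings::score(al)
        if (sc < min_score) next
        s <- Biostrings::start(Biostrings::subject(al))
        e <- Biostrings::end(Biostrings::subject(al))
        nt <- frame_to_forward(s, e, fr$offset, fr$strand, n)
        hits[[length(hits) + 1L]] <- data.frame(
          contig_id = cid, gene = g, score = sc, strand = fr$strand,
          frame = fr$offset, start = nt[["start"]], end = nt[["end"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, c(hits, list(make.row.names = FALSE)))
         else data.frame(contig_id = character(0), gene = character(0),
                         score = numeric(0), strand = character(0),
                         frame = integer(0), start = integer(0),
                         end = integer(0))
  if (!nrow(out)) message("no mitochondrial seed contigs found")
  attr(out, "seeds") <- unique(out$contig_id)
  out
}

#' Classify contigs as mitochondrial by coverage/GC proximity to seeds
#'
#' Non-seed contigs are labelled `mito` iff their coverage lies within a
#' multiplicative band of the median seed coverage and their GC within an
#' absolute window of the median seed GC; seeds are always `mito`.
#'
#' @param stats data.frame from [contig_stats()].
#' @param seeds character vector of seed contig ids (nonempty).
#' @param cov_factor multiplicative coverage band (default 2).
#' @param gc_window absolute GC window (default 0.08).
#' @return `stats` with an added `label` column (`"mito"`/`"other"`).
#' @export
blob_classify <- function(stats, seeds, cov_factor = 2, gc_window = 0.08) {
  if (!length(seeds)) stop("blob_classify needs at least one seed contig")
  if (length(seeds) == 1L)
    warning("single seed contig: coverage/GC band computed from one value")
  sd_ <- stats[stats$contig_id %in% seeds, ]
  med_cov <- stats::median(sd_$coverage)
  med_gc <- stats::median(sd_$gc)
  in_band <- stats$coverage >= med_cov / cov_factor &
    stats$coverage <= med_cov * cov_factor &
    abs(stats$gc - med_gc) <= gc_window
  stats$label <- ifelse(stats$contig_id %in% seeds | in_band, "mito", "other")
  stats
}

#' Write a blob table (contig_id, length, coverage, gc, label) to TSV
#' @param stats labelled data.frame from [blob_classify()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blob_table <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Iterative bait-and-extend assembly
#'
#' Starting from a seed sequence, each round recruits every unrecruited read
#' (either orientation) whose best ungapped placement overlaps the current
#' consensus by at least `min_overlap` nt with a mismatch fraction at most
#' `max_mismatch_frac` (no gaps). The consensus is then extended at both ends
#' by per-column majority vote over recruited reads overhanging the ends
#' (ties toward the lexicographically smallest base). Mapping is repeated
#' until no further reads can be recruited, or `max_rounds` is reached.
#'
#' @param reads character vector of reads; names are read ids (made unique if
#'   missing or duplicated).
#' @param seed_seq the bait sequence (>= `min_overlap` nt).
#' @param min_overlap minimum overlap in nt (default 100).
#' @param max_mismatch_frac maximum mismatches/overlap (default 0.01).
#' @param allow_gaps must be FALSE; gapped recruitment is not supported.
#' @param max_rounds round cap.
#' @return an `assembly_state`: list with `consensus`, `recruited_read_ids`,
#'   `round`, `converged`.
#' @export
bait_extend_iterate <- function(reads, seed_seq, min_overlap = 100L,
                                max_mismatch_frac = 0.01, allow_gaps = FALSE,
                                max_rounds = 1000L) {
  if (isTRUE(allow_gaps)) stop("gapped recruitment is not supported")
  stopifnot(length(reads) > 0, nchar(seed_seq) >= min_overlap)
  ids <- names(reads)
  if (is.null(ids) || anyDuplicated(ids))
    ids <- sprintf("read%06d", seq_along(reads))
  fwd <- unname(reads)
  rc <- revcomp_many(fwd)
  seed_tab <- build_seed_table(fwd, rc)
  lens <- nchar(fwd)

  consensus <- toupper(seed_seq)
  recruited <- logical(length(reads))
  diag_of <- integer(length(reads))    # placement of each recruited read
  rc_of <- logical(length(reads))
  round_i <- 0L
  converged <- FALSE

  while (round_i < max_rounds) {
    round_i <- round_i + 1L
    L <- nchar(consensus)
    hits <- ungapped_best_hits(consensus, fwd, rc, seed_tab,
                               live = which(!recruited),
                               min_overlap, max_mismatch_frac)
    if (!nrow(hits)) {
      converged <- TRUE
      break
    }
    recruited[hits$read] <- TRUE
    diag_of[hits$read] <- hits$diag
    rc_of[hits$read] <- hits$rcflag == 1L

    # extend both ends by majority vote over overhanging recruited reads
    rec <- which(recruited)
    diags <- diag_of[rec]
    seqs <- ifelse(rc_of[rec], rc[rec], fwd[rec])
    right_over <- diags + lens[rec] - 1L - L
    left_over <- 1L - diags
    ext_right <- majority_overhang(seqs[right_over > 0],
                                   overhang = right_over[right_over > 0],
                                   side = "right")
    ext_left <- majority_overhang(seqs[left_over > 0],
                                  overhang = left_over[left_over > 0],
                                  side = "left")
    if (nzchar(ext_right)) consensus <- paste0(consensus, ext_right)
    if (nzchar(ext_left)) {
      consensus <- paste0(ext_left, consensus)
      diag_of[recruited] <- diag_of[recruited] + nchar(ext_left)
    }
  }

  structure(list(consensus = consensus,
                 recruited_read_ids = ids[recruited],
                 round = round_i, converged = converged),
            class = "assembly_state")
}

# Majority vote over read overhangs at one end. seqs are read sequences in
# consensus orientation; overhang[i] gives how many of their terminal bases
# extend past the end. Ties break to the lexicographically smallest base.
majority_overhang <- function(seqs, overhang, side = c("right", "left")) {
  side <- match.arg(side)
  if (!length(seqs)) return("")
  parts <- vapply(seq_along(seqs), function(i) {
    n <- nchar(seqs[i])
    if (side == "right") substr(seqs[i], n - overhang[i] + 1L, n)
    else substr(seqs[i], 1L, overhang[i])
  }, character(1))
  width <- max(overhang)
  cols <- character(width)
  for (j in seq_len(width)) {
    votes <- vapply(seq_along(parts), function(i) {
      k <- overhang[i]
      if (k < j) return(NA_character_)
      if (side == "right") substr(parts[i], j, j)
      else substr(parts[i], k - j + 1L, k - j + 1L)
    }, character(1))
    votes <- votes[!is.na(votes)]
    if (!length(votes)) { width <- j - 1L; break }
    tt <- table(votes)
    cols[j] <- names(tt)[which.max(tt)]    # ties: first name = smallest base
  }
  cols <- cols[seq_len(width)]
  if (!length(cols)) return("")
  if (side == "right") paste(cols, collapse = "")
  else paste(rev(cols), collapse = "")
}

#' Detect and trim a circular-mapping consensus
#'
#' The consensus is circular iff a suffix of length at least
#' `min_end_overlap` exactly matches a prefix; the duplicated terminus is
#' trimmed once.
#'
#' @param consensus DNA string (>= 2*min_end_overlap nt).
#' @param min_end_overlap minimum exact end duplication (default 50).
#' @return list(is_circular, seq) where `seq` is trimmed when circular.
#' @export
circularize <- function(consensus, min_end_overlap = 50L) {
  assert_dna(consensus, "consensus")
  L <- nchar(consensus)
  stopifnot(L >= 2L * min_end_overlap)
  probe <- substr(consensus, 1L, min_end_overlap)
  occ <- gregexpr(probe, consensus, fixed = TRUE)[[1]]
  occ <- occ[occ > 1L]
  best_k <- 0L
  for (p in occ) {
    k <- L - p + 1L
    if (k < min_end_overlap || k >= L) next
    if (substr(consensus, p, L) == substr(consensus, 1L, k))
      best_k <- max(best_k, k)
  }
  if (best_k == 0L) return(list(is_circular = FALSE, seq = consensus))
  list(is_circular = TRUE, seq = substr(consensus, 1L, L - best_k))
}
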