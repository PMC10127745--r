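# Gene annotation on mitochondrial contigs by translated homology, plus the
# secondary structures seen in retarian mitogenomes: split genes, intergenic
# pseudogene fragments (>= 4 distinct supporting panel taxa), ~50-bp
# pseudorepeat families, and single-nucleotide-insertion frameshift repair.

# Local protein alignment (Smith-Waterman, BLOSUM62, affine gaps). Returns
# score plus 1-based aligned intervals in pattern (reference) and subject.
# With trim = TRUE, alignment ends are trimmed back to the outermost window
# of `trim_w` columns with identity >= trim_ident: AT-rich translations have
# a biased composition under which unrelated sequence can accumulate a
# positive BLOSUM score, so untrimmed local alignments occasionally chain
# junk segments onto a genuine hit and overstate the aligned interval.
align_local <- function(ref, subject, trim = FALSE, trim_w = 15L,
                        trim_ident = 0.4) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ref), Biostrings::AAString(subject), type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  out <- list(score = Biostrings::score(al),
              ref_start = Biostrings::start(Biostrings::pattern(al)),
              ref_end = Biostrings::end(Biostrings::pattern(al)),
              sub_start = Biostrings::start(Biostrings::subject(al)),
              sub_end = Biostrings::end(Biostrings::subject(al)))
  if (!trim || out$score <= 0) return(out)
  p <- strsplit(as.character(Biostrings::pattern(al)), "", fixed = TRUE)[[1]]
  s <- strsplit(as.character(Biostrings::subject(al)), "", fixed = TRUE)[[1]]
  n <- length(p)
  if (n < trim_w) return(out)
  ident <- as.numeric(p == s & p != "-")
  win <- stats::filter(ident, rep(1 / trim_w, trim_w), sides = 1)  # mean of [i-w+1, i]
  good_end <- which(win >= trim_ident)           # window ending at i is good
  if (!length(good_end)) return(out)
  first <- min(good_end) - trim_w + 1L
  last <- max(good_end)
  if (first > 1L) {
    out$ref_start <- out$ref_start + sum(p[seq_len(first - 1L)] != "-")
    out$sub_start <- out$sub_start + sum(s[seq_len(first - 1L)] != "-")
  }
  if (last < n) {
    out$ref_end <- out$ref_end - sum(p[(last + 1L):n] != "-")
    out$sub_end <- out$sub_end - sum(s[(last + 1L):n] != "-")
  }
  out
}

#' Annotate protein-coding genes by translated homology
#'
#' Aligns each gene's panel consensus protein locally against all six frame
#' translations of the contig (stops rendered as X). Hits scoring at or above
#' `min_score` become annotations; within a frame the best hit is masked and
#' the frame realigned once, so two separated segments of the same gene (a
#' split gene) are both found. Annotations whose aligned reference coverage
#' is below `full_cov` are typed `gene_fragment_candidate` rather than
#' `gene`.
#'
#' @param contig DNA string.
#' @param panel `ortho_panel` or named list with per-gene `taxa`.
#' @param code genetic code for translation.
#' @param contig_id id used in the output.
#' @param min_score minimum local alignment score.
#' @param full_cov minimum coverage_of_reference for a full gene call.
#' @return data.frame: gene, contig_id, start, end (0-based half-open),
#'   strand, frame, split_part, score, coverage_of_reference, ref_start,
#'   ref_end (1-based aa), type.
#' @export
annotate_by_homology <- function(contig, panel, code = genetic_code("table4"),
                                 contig_id = "contig1", min_score = 100,
                                 full_cov = 0.6) {
  empty <- data.frame(gene = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      split_part = character(0), score = numeric(0),
                      coverage_of_reference = numeric(0),
                      ref_start = integer(0), ref_end = integer(0),
                      type = character(0))
  if (is.null(contig) || !nzchar(contig)) return(empty)
  refs <- lapply(panel, function(g) panel_consensus(g$taxa %||% g))
  n <- nchar(contig)
  frames <- six_frames(contig, code)
  out <- list()
  for (g in names(refs)) {
    ref <- refs[[g]]
    rlen <- nchar(ref)
    for (fr in frames) {
      prot <- fr$protein
      if (nchar(prot) < 10L) next
      for (pass in 1:2) {
        al <- align_local(ref, prot, trim = TRUE)
        if (al$score < min_score) break
        nt <- frame_to_forward(al$sub_start, al$sub_end, fr$offset,
                               fr$strand, n)
        cov <- (al$ref_end - al$ref_start + 1L) / rlen
        out[[length(out) + 1L]] <- data.frame(
          gene = g, contig_id = contig_id,
          start = nt[["start"]], end = nt[["end"]],
          strand = fr$strand, frame = fr$offset,
          split_part = NA_character_, score = al$score,
          coverage_of_reference = cov,
          ref_start = al$ref_start, ref_end = al$ref_end,
          stringsAsFactors = FALSE)
        # mask the hit and look for a second same-frame segment
        substr(prot, al$sub_start, al$sub_end) <-
          paste(rep("X", al$sub_end - al$sub_start + 1L), collapse = "")
      }
    }
  }
  if (!length(out)) return(empty)
  ann <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  # drop same-gene hits overlapping a better hit on the contig
  keep <- rep(TRUE, nrow(ann))
  ord <- order(-ann$score)
  for (i in seq_along(ord)) {
    a <- ord[i]
    if (!keep[a]) next
    for (b in ord[-seq_len(i)]) {
      if (!keep[b] || ann$gene[b] != ann$gene[a]) next
      if (ann$start[b] < ann$end[a] && ann$start[a] < ann$end[b])
        keep[b] <- FALSE
    }
  }
  ann <- ann[keep, , drop = FALSE]
  ann$type <- ifelse(ann$coverage_of_reference >= full_cov,
                     "gene", "gene_fragment_candidate")
  ann <- ann[order(ann$start, ann$end), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Flag split genes
#'
#' Two same-gene annotations whose aligned reference intervals are
#' complementary — combined reference coverage at least `combined_cov` with
#' reference overlap at most `max_ref_overlap` of the reference length — are
#' flagged as split parts 1 and 2 in reference order. Same-gene pairs that
#' both cover most of the reference are duplicates, not splits.
#'
#' @param ann annotations from [annotate_by_homology()].
#' @param combined_cov minimum combined reference coverage (default 0.8).
#' @param max_ref_overlap maximum reference-interval overlap as a fraction of
#'   the reference length (default 0.1).
#' @param ref_lengths named vector of reference protein lengths (aa); taken
#'   from `ref_end / coverage_of_reference` when omitted.
#' @return `ann` with `split_part` set to "1"/"2" where detected.
#' @export
detect_split_genes <- function(ann, combined_cov = 0.8, max_ref_overlap = 0.1,
                               ref_lengths = NULL) {
  if (!nrow(ann)) return(ann)
  for (g in unique(ann$gene)) {
    idx <- which(ann$gene == g)
    if (length(idx) < 2L) next
    rlen <- if (!is.null(ref_lengths)) ref_lengths[[g]]
            else round((ann$ref_end[idx[1]] - ann$ref_start[idx[1]] + 1L) /
                         ann$coverage_of_reference[idx[1]])
    # best complementary pair
    best <- NULL
    for (i in idx) for (j in idx) {
      if (i >= j) next
      ov <- max(0L, min(ann$ref_end[i], ann$ref_end[j]) -
                     max(ann$ref_start[i], ann$ref_start[j]) + 1L)
      comb <- (ann$ref_end[i] - ann$ref_start[i] + 1L +
                 ann$ref_end[j] - ann$ref_start[j] + 1L - ov) / rlen
      if (comb >= combined_cov && ov / rlen <= max_ref_overlap &&
          (is.null(best) || comb > best$comb))
        best <- list(i = i, j = j, comb = comb)
    }
    if (!is.null(best)) {
      first <- if (ann$ref_start[best$i] <= ann$ref_start[best$j]) best$i
               else best$j
      second <- setdiff(c(best$i, best$j), first)
      ann$split_part[first] <- "1"
      ann$split_part[second] <- "2"
    }
  }
  ann
}

#' Intergenic regions as the complement of annotated spans
#'
#' @param contig_len contig length (nt).
#' @param ann annotation data.frame with start/end (0-based half-open).
#' @param min_len drop regions shorter than this (default 1).
#' @return data.frame with start, end (0-based half-open).
#' @export
intergenic_regions <- function(contig_len, ann, min_len = 1L) {
  if (!nrow(ann))
    return(data.frame(start = 0L, end = contig_len)[contig_len >= min_len, ,
                                                    drop = FALSE])
  ir <- IRanges::reduce(IRanges::IRanges(ann$start + 1L, ann$end))
  gaps <- IRanges::gaps(ir, start = 1L, end = contig_len)
  out <- data.frame(start = IRanges::start(gaps) - 1L,
                    end = IRanges::end(gaps))
  out[out$end - out$start >= min_len, , drop = FALSE]
}

# Null score threshold for translated fragment searches: local-alignment
# scores of shuffled frame translations against panel proteins.
calibrate_null_threshold <- function(frame_prots, panel_prots,
                                     quantile = 0.99, n_null = 60L) {
  frame_prots <- frame_prots[nchar(frame_prots) >= 10L]
  if (!length(frame_prots) || !length(panel_prots)) return(Inf)
  scores <- numeric(0)
  i <- 0L
  while (length(scores) < n_null) {
    i <- i + 1L
    fp <- frame_prots[[((i - 1L) %% length(frame_prots)) + 1L]]
    pp <- panel_prots[[((i - 1L) %% length(panel_prots)) + 1L]]
    shuf <- paste(sample(strsplit(fp, "", fixed = TRUE)[[1]]), collapse = "")
    scores <- c(scores, align_local(pp, shuf)$score)
  }
  stats::quantile(scores, quantile, names = FALSE)
}

#' Scan intergenic regions for pseudogene fragments
#'
#' Each intergenic region is translated in six frames and searched against
#' every panel taxon's protein for candidate genes. A region is annotated as
#' a fragment of gene g iff at least `min_taxa` distinct panel taxa hit it
#' for g with a local alignment score above an empirically calibrated null
#' threshold (quantile of scores of shuffled translations).
#'
#' @param contig DNA string.
#' @param ann gene annotations defining the intergenic complement.
#' @param panel `ortho_panel` or named list with per-gene `taxa`.
#' @param code genetic code for translation.
#' @param min_taxa minimum distinct supporting taxa (default 4).
#' @param min_region_len skip regions shorter than this (default 60 nt).
#' @param threshold score threshold; `NULL` to calibrate from shuffles.
#' @param threshold_quantile null quantile used when calibrating.
#' @param min_score floor under the calibrated threshold: AT-rich junk
#'   translations share the biased composition of genuine mitochondrial
#'   proteins, so raw scores below this are never treated as hits
#'   (comparable to a marginal blastx significance at panel-search sizes).
#' @param contig_id id used in the output.
#' @return data.frame of fragment hits: contig_id, start, end, gene,
#'   n_supporting_taxa, mean_score, threshold.
#' @export
scan_intergenic_fragments <- function(contig, ann, panel,
                                      code = genetic_code("table4"),
                                      min_taxa = 4L, min_region_len = 60L,
                                      threshold = NULL,
                                      threshold_quantile = 0.99,
                                      min_score = 90,
                                      contig_id = "contig1") {
  stopifnot(min_taxa >= 1L)
  regions <- intergenic_regions(nchar(contig), ann, min_len = min_region_len)
  empty <- data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), gene = character(0),
                      n_supporting_taxa = integer(0), mean_score = numeric(0),
                      threshold = numeric(0))
  if (!nrow(regions)) return(empty)
  taxa_sets <- lapply(panel, function(g) g$taxa %||% g)
  refs <- lapply(taxa_sets, panel_consensus)
  out <- list()
  for (r in seq_len(nrow(regions))) {
    rseq <- substr(contig, regions$start[r] + 1L, regions$end[r])
    frames <- six_frames(rseq, code)
    prots <- vapply(frames, `[[`, "", "protein")
    prots <- prots[nchar(prots) >= 10L]
    if (!length(prots)) next
    thr <- threshold %||%
      max(calibrate_null_threshold(prots, unlist(lapply(taxa_sets, `[`, 1L)),
                                   quantile = threshold_quantile), min_score)
    # stage 1: candidate genes via the panel consensus
    cand <- names(refs)[vapply(names(refs), function(g)
      max(vapply(prots, function(p) align_local(refs[[g]], p)$score,
                 numeric(1))) >= thr, logical(1))]
    # stage 2: distinct-taxon support
    for (g in cand) {
      sc <- vapply(taxa_sets[[g]], function(tp)
        max(vapply(prots, function(p) align_local(tp, p)$score, numeric(1))),
        numeric(1))
      supp <- sum(sc >= thr)
      if (supp >= min_taxa)
        out[[length(out) + 1L]] <- data.frame(
          contig_id = contig_id, start = regions$start[r],
          end = regions$end[r], gene = g, n_supporting_taxa = supp,
          mean_score = mean(sc[sc >= thr]), threshold = thr,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Detect ~50-bp pseudorepeat families
#'
#' Finds families of two or more approximately repeated units of about
#' `unit_len` nt in which every occurrence is within `max_mismatch`
#' substitutions of the family consensus. Candidate families are anchored on
#' exact shared k-mers, occurrences are placed greedily without overlap, and
#' family boundaries may extend up to `unit_len + unit_tol` while the
#' occurrences keep agreeing.
#'
#' @param seq DNA string (>= `unit_len` nt).
#' @param unit_len nominal repeat unit length (default 50).
#' @param unit_tol boundary extension tolerance in nt (default 10).
#' @param max_mismatch maximum mismatches of an occurrence vs the family
#'   consensus (default 2).
#' @return list of families: each has `unit_length`, `consensus`,
#'   `max_mismatches_observed`, and `occurrences` (data.frame start, end —
#'   0-based half-open — and mismatches vs the consensus).
#' @export
detect_pseudorepeats <- function(seq, unit_len = 50L, unit_tol = 10L,
                                 max_mismatch = 2L) {
  assert_dna(seq)
  L <- nchar(seq)
  stopifnot(L >= unit_len)
  k <- max(8L, unit_len %/% (max_mismatch + 1L) - 2L)
  pos <- seq_len(L - k + 1L)
  kmers <- substring(seq, pos, pos + k - 1L)
  dup_kmers <- unique(kmers[duplicated(kmers)])
  covered <- logical(L)
  families <- list()

  occ_of_unit <- function(unit, tol) {
    # pigeonhole: with <= tol mismatches, one of tol+1 chunks matches exactly
    ulen <- nchar(unit)
    clen <- ulen %/% (tol + 1L)
    starts <- integer(0)
    for (ci in seq_len(tol + 1L)) {
      coff <- (ci - 1L) * clen
      chunk <- substr(unit, coff + 1L, coff + clen)
      hits <- gregexpr(chunk, seq, fixed = TRUE)[[1]]
      if (hits[1] == -1L) next
      starts <- c(starts, hits - coff)
    }
    starts <- sort(unique(starts[starts >= 1L & starts + ulen - 1L <= L]))
    cand <- starts[vapply(starts, function(s)
      !any(covered[s:(s + ulen - 1L)]) &&
        str_mismatches(substr(seq, s, s + ulen - 1L), unit) <= tol,
      logical(1))]
    # greedy non-overlapping placement
    kept <- integer(0)
    last_end <- 0L
    for (s in cand) {
      if (s > last_end) {
        kept <- c(kept, s)
        last_end <- s + ulen - 1L
      }
    }
    kept
  }

  consensus_of <- function(starts, ulen) {
    mat <- do.call(rbind, strsplit(substring(seq, starts, starts + ulen - 1L),
                                   "", fixed = TRUE))
    paste(apply(mat, 2L, function(col) {
      tt <- table(col)
      names(tt)[which.max(tt)]
    }), collapse = "")
  }

  for (km in dup_kmers) {
    p <- pos[kmers == km]
    p <- p[!covered[p]]
    if (length(p) < 2L) next
    p1 <- p[1]
    # locate the unit window around the anchor: choose the offset that
    # minimises mismatches between the first two copies
    best <- NULL
    for (delta in 0:(unit_len - k)) {
      s1 <- p1 - delta
      s2 <- p[2] - delta
      if (s1 < 1L || s2 + unit_len - 1L > L) next
      mm <- str_mismatches(substr(seq, s1, s1 + unit_len - 1L),
                           substr(seq, s2, s2 + unit_len - 1L))
      if (is.null(best) || mm < best$mm) best <- list(s = s1, mm = mm)
    }
    if (is.null(best) || best$mm > 2L * max_mismatch) next
    # a single occurrence can be max_mismatch away from the family consensus
    # in either direction, so seed the search at twice the bound, refine the
    # consensus, then re-collect occurrences against the refined consensus
    unit <- substr(seq, best$s, best$s + unit_len - 1L)
    starts <- occ_of_unit(unit, 2L * max_mismatch)
    if (length(starts) < 2L) next
    for (pass in 1:2) {
      cons <- consensus_of(starts, unit_len)
      starts <- occ_of_unit(cons, max_mismatch)
      if (length(starts) < 2L) break
    }
    if (length(starts) < 2L) next
    cons <- consensus_of(starts, unit_len)
    mm <- vapply(starts, function(s)
      str_mismatches(substr(seq, s, s + unit_len - 1L), cons), integer(1))
    starts <- starts[mm <= max_mismatch]
    if (length(starts) < 2L) next
    cons <- consensus_of(starts, unit_len)
    mm <- vapply(starts, function(s)
      str_mismatches(substr(seq, s, s + unit_len - 1L), cons), integer(1))

    # extend boundaries while occurrences keep agreeing (up to unit_tol)
    ulen <- unit_len
    while (ulen < unit_len + unit_tol &&
           all(starts + ulen <= L)) {
      nxt <- substring(seq, starts + ulen, starts + ulen)
      tt <- table(nxt)
      agree <- max(tt) / length(nxt)
      if (agree < 1) break
      ulen <- ulen + 1L
    }
    if (ulen > unit_len) {
      cons <- consensus_of(starts, ulen)
      mm <- vapply(starts, function(s)
        str_mismatches(substr(seq, s, s + ulen - 1L), cons), integer(1))
    }
    for (s in starts) covered[s:(s + ulen - 1L)] <- TRUE
    families[[length(families) + 1L]] <- list(
      unit_length = ulen, consensus = cons,
      max_mismatches_observed = max(mm),
      occurrences = data.frame(start = starts - 1L, end = starts - 1L + ulen,
                               mismatches = mm))
  }
  families
}

#' Repair a single-nucleotide-insertion frameshift
#'
#' Exhaustively tries inserting one N at every position of the region and
#' keeps the positions at which the repaired in-frame translation (i) aligns
#' to at least `min_cov` of the reference protein and (ii) contains no
#' terminator codon within the aligned span (the N codon translates to X and
#' is ignored). Calls are returned best-first by alignment score; if the
#' accepted positions form more than one disjoint window the result is
#' flagged ambiguous. Regions that already align at `min_cov` without repair
#' yield no calls.
#'
#' Two candidate insertion points can differ in score by at most one aligned
#' residue — bounded by the largest BLOSUM62 diagonal entry (11) plus the X
#' placeholder penalty — so calls within 13 score points of the best are
#' indistinguishable at single-residue resolution and together form the
#' repair window (the true position is resolvable to the codon, not the
#' base, and score ties extend one codon either way).
#'
#' @param region in-frame DNA string covering the suspect gene.
#' @param reference_protein the reference (e.g. panel consensus) protein.
#' @param code genetic code used for translation.
#' @param min_cov minimum aligned fraction of the reference (default 0.9).
#' @param require_stop_free enforce the no-terminator condition; set FALSE
#'   for genomes whose code is suspected of stop-codon readthrough, where
#'   in-frame focal codons cannot disqualify a repair.
#' @return data.frame: insert_pos (0-based nt), codon_index, score,
#'   coverage, ambiguous.
#' @export
repair_single_insertion_frameshift <- function(region, reference_protein,
                                               code = genetic_code("table4"),
                                               min_cov = 0.9,
                                               require_stop_free = TRUE) {
  assert_dna(region, "region")
  empty <- data.frame(insert_pos = integer(0), codon_index = integer(0),
                      score = numeric(0), coverage = numeric(0),
                      ambiguous = logical(0))
  n <- nchar(region)
  rlen <- nchar(reference_protein)
  trim <- function(s) substr(s, 1L, (nchar(s) %/% 3L) * 3L)
  base_tr <- translate_cds(trim(region), code, readthrough = "all_stops_as_X")
  base_al <- align_local(reference_protein, base_tr$protein)
  if ((base_al$ref_end - base_al$ref_start + 1L) / rlen >= min_cov)
    return(empty)

  cands <- vapply(0:n, function(p) {
    paste0(substr(region, 1L, p), "N", substr(region, p + 1L, n))
  }, character(1))
  trs <- lapply(cands, function(s)
    translate_cds(trim(s), code, readthrough = "all_stops_as_X"))
  prots <- vapply(trs, `[[`, "", "protein")
  als <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(prots),
    Biostrings::AAString(reference_protein), type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  scores <- Biostrings::score(als)
  qs <- Biostrings::start(Biostrings::pattern(als))
  qe <- Biostrings::end(Biostrings::pattern(als))
  rs <- Biostrings::start(Biostrings::subject(als))
  re <- Biostrings::end(Biostrings::subject(als))
  cov <- (re - rs + 1L) / rlen

  # terminator codons ('*' in the code table) inside the aligned query span
  stop_free <- if (require_stop_free) vapply(seq_along(trs), function(i) {
    st <- trs[[i]]$stops + 1L
    st <- st[code$table[split_codons(trim(cands[i]))[st]] == STOP_CHAR]
    !any(st >= qs[i] & st <= qe[i])
  }, logical(1)) else rep(TRUE, length(trs))

  ok <- which(cov >= min_cov & stop_free)
  if (!length(ok)) return(empty)
  pos <- ok - 1L                      # insertion position, 0-based
  ambiguous <- any(diff(sort(pos)) > 3L)
  out <- data.frame(insert_pos = pos, codon_index = pos %/% 3L,
                    score = scores[ok], coverage = cov[ok],
                    ambiguous = ambiguous)
  out[order(-out$score), , drop = FALSE]
}

#' Summarise coding content of an annotated contig
#'
#' @param contig_len contig length (nt).
#' @param ann annotations (0-based half-open spans).
#' @return list with `coding_fraction`, `gene_order` (genes in genome
#'   order), and `intergenic` (data.frame of intergenic spans with lengths).
#' @export
coding_summary <- function(contig_len, ann) {
  if (!nrow(ann))
    return(list(coding_fraction = 0,
                gene_order = character(0),
                intergenic = data.frame(start = 0L, end = contig_len,
                                        length = contig_len)))
  ir <- IRanges::reduce(IRanges::IRanges(ann$start + 1L, ann$end))
  coding <- sum(IRanges::width(ir))
  inter <- intergenic_regions(contig_len, ann)
  inter$length <- inter$end - inter$start
  list(coding_fraction = coding / contig_len,
       gene_order = ann$gene[order(ann$start)],
       intergenic = inter)
}

#' Export annotations to GFF3
#'
#' Writes gene, pseudogene_fragment, repeat_region and frameshift features
#' with 1-based inclusive coordinates.
#'
#' @param path output file.
#' @param contig_lengths named vector of contig lengths.
#' @param ann gene annotations (may be NULL).
#' @param fragments fragment hits (may be NULL).
#' @param repeats pseudorepeat family list (may be NULL).
#' @param frameshift frameshift record with contig_id/contig_pos (may be NULL).
#' @param repeat_contig contig id for repeat features.
#' @return `path`, invisibly.
#' @export
export_gff3 <- function(path, contig_lengths, ann = NULL, fragments = NULL,
                        repeats = NULL, frameshift = NULL,
                        repeat_contig = NULL) {
  grl <- list()
  if (!is.null(ann) && nrow(ann)) {
    nm <- ifelse(is.na(ann$split_part), ann$gene,
                 paste0(ann$gene, "_part", ann$split_part))
    grl$genes <- GenomicRanges::GRanges(
      ann$contig_id, IRanges::IRanges(ann$start + 1L, ann$end),
      strand = ann$strand, type = ann$type, ID = nm, Name = ann$gene,
      score = ann$score)
    grl$genes$type <- ifelse(ann$type == "gene", "gene", "pseudogene_fragment")
  }
  if (!is.null(fragments) && nrow(fragments))
    grl$frag <- GenomicRanges::GRanges(
      fragments$contig_id, IRanges::IRanges(fragments$start + 1L,
                                            fragments$end),
      strand = "*", type = "pseudogene_fragment",
      ID = paste0(fragments$gene, "_frag", seq_len(nrow(fragments))),
      Name = fragments$gene, score = fragments$mean_score)
  if (!is.null(repeats) && length(repeats)) {
    occ <- do.call(rbind, lapply(seq_along(repeats), function(i)
      cbind(repeats[[i]]$occurrences, fam = i)))
    grl$rep <- GenomicRanges::GRanges(
      repeat_contig %||% names(contig_lengths)[1],
      IRanges::IRanges(occ$start + 1L, occ$end), strand = "*",
      type = "repeat_region",
      ID = sprintf("repfam%d_occ%d", occ$fam, seq_len(nrow(occ))),
      Name = sprintf("repeat_family_%d", occ$fam), score = NA_real_)
  }
  if (!is.null(frameshift))
    grl$fs <- GenomicRanges::GRanges(
      frameshift$contig_id,
      IRanges::IRanges(frameshift$contig_pos + 1L, frameshift$contig_pos + 1L),
      strand = "*", type = "frameshift",
      ID = paste0(frameshift$gene, "_frameshift"), Name = frameshift$gene,
      score = NA_real_)
  gr <- do.call(c, unname(grl))
  if (is.null(gr)) gr <- GenomicRanges::GRanges()
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
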