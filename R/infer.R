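# Genetic-code inference from in-frame stop codons. Every internal TGA, TAG
# and TAA of a query coding sequence is mapped through a query-vs-panel
# protein alignment onto a reference column; the >50% consensus residues of
# the counted columns are tallied per codon and grouped by biochemical
# property; terminal-codon usage is profiled; and the three verdicts
# (sense / stop / dual-role) are combined into an inferred genetic code.

#' Biochemical property classes of the 20 amino acids
#'
#' Default grouping: aromatic F, W, Y, H; charged D, E, K, R; polar S, T, N,
#' Q, C; nonpolar G, A, V, L, I, P, M. Histidine is grouped aromatic; the
#' grouping is configurable because no single standard exists.
#'
#' @param aromatic,charged,polar,nonpolar character vectors partitioning the
#'   20 amino acids.
#' @return named character vector mapping each amino acid to its class.
#' @export
property_classes <- function(aromatic = c("F", "W", "Y", "H"),
                             charged = c("D", "E", "K", "R"),
                             polar = c("S", "T", "N", "Q", "C"),
                             nonpolar = c("G", "A", "V", "L", "I", "P", "M")) {
  map <- c(stats::setNames(rep("aromatic", length(aromatic)), aromatic),
           stats::setNames(rep("charged", length(charged)), charged),
           stats::setNames(rep("polar", length(polar)), polar),
           stats::setNames(rep("nonpolar", length(nonpolar)), nonpolar))
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!setequal(names(map), aas) || length(map) != 20L)
    stop("property classes must cover each of the 20 amino acids exactly once")
  map
}

# Hydrophobic residue set used by the pairwise stop profile.
HYDROPHOBIC_AA <- c("A", "V", "L", "I", "M", "F", "W", "Y", "C")

# Render a query CDS for alignment: the three standard stop codons become X
# placeholders; the returned stop list gives their internal 0-based codon
# indices (a terminal focal codon is excluded — it is the terminator).
query_protein_for_msa <- function(seq) {
  tr <- translate_cds(seq, genetic_code("standard"),
                      readthrough = "all_stops_as_X")
  n_codons <- nchar(seq) %/% 3L
  stops <- tr$stops
  internal <- stops[stops < n_codons - 1L]
  list(protein = tr$protein, internal_stops = internal,
       codons = split_codons(seq))
}

#' Align a query protein into a reference panel alignment
#'
#' The query (with X placeholders at stop positions) is aligned globally
#' against the panel consensus (Needleman-Wunsch, BLOSUM62, affine gaps) and
#' the panel rows are expanded with all-gap columns at query insertions, so
#' every query codon maps to exactly one alignment column.
#'
#' @param query_protein query protein string (placeholders allowed).
#' @param panel_taxa named character vector of mutually aligned panel
#'   proteins (equal length; gaps allowed).
#' @param aligner optional function(query, ref) returning a list with
#'   elements `pattern` and `subject`: the two aligned strings. Defaults to
#'   Biostrings global alignment.
#' @return list with `query` (chars incl. gaps), `panel` (taxa x columns
#'   character matrix), `col_of_codon` (1-based column of each query
#'   residue), `n_col`.
#' @export
build_gene_msa <- function(query_protein, panel_taxa, aligner = NULL) {
  stopifnot(length(panel_taxa) >= 1L)
  widths <- nchar(panel_taxa)
  if (length(unique(widths)) != 1L)
    stop("panel proteins must be mutually aligned (equal width)")
  ref <- panel_consensus(panel_taxa)
  if (is.null(aligner)) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(query_protein), Biostrings::AAString(ref),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1)
    pat <- as.character(Biostrings::alignedPattern(al))
    sub <- as.character(Biostrings::alignedSubject(al))
  } else {
    res <- aligner(query_protein, ref)
    pat <- res$pattern
    sub <- res$subject
  }
  qchars <- strsplit(pat, "", fixed = TRUE)[[1]]
  rchars <- strsplit(sub, "", fixed = TRUE)[[1]]
  if (length(qchars) != length(rchars))
    stop("aligner returned strings of unequal length")
  pmat <- do.call(rbind, strsplit(unname(panel_taxa), "", fixed = TRUE))
  rownames(pmat) <- names(panel_taxa)
  # expand panel with all-gap columns where the query has an insertion
  ncol_aln <- length(qchars)
  out <- matrix("-", nrow = nrow(pmat), ncol = ncol_aln,
                dimnames = list(rownames(pmat), NULL))
  ref_i <- 0L
  for (j in seq_len(ncol_aln)) {
    if (rchars[j] != "-") {
      ref_i <- ref_i + 1L
      out[, j] <- pmat[, ref_i]
    }
  }
  col_of_codon <- which(qchars != "-")
  list(query = qchars, panel = out, col_of_codon = col_of_codon,
       n_col = ncol_aln)
}

#' Consensus residue of an alignment column
#'
#' The consensus is the unique most frequent residue among non-gap panel
#' rows, and only if its frequency strictly exceeds `threshold`; ties or
#' sub-threshold modes give no consensus. The query row must not be included.
#'
#' @param column character vector of panel residues ("-" for gap).
#' @param threshold consensus frequency threshold (default 0.5, strict).
#' @return list with `aa` (residue or NA), `occupancy` (non-gap fraction),
#'   `gap_fraction`.
#' @export
column_consensus <- function(column, threshold = 0.5) {
  n <- length(column)
  res <- column[column != "-" & column != "X"]
  occ <- length(res) / n
  out <- list(aa = NA_character_, occupancy = occ, gap_fraction = 1 - occ)
  if (!length(res)) return(out)
  tt <- sort(table(res), decreasing = TRUE)
  if (tt[1] / length(res) > threshold &&
      (length(tt) == 1L || tt[1] > tt[2]))
    out$aa <- names(tt)[1]
  out
}

#' Map internal stop codons onto alignment columns
#'
#' Every internal occurrence of TGA/TAG/TAA in each CDS (the terminal
#' terminator excluded) becomes one stop site with a status: `excluded_gap`
#' when the column is majority-gap in the panel, `excluded_sparse` when
#' panel occupancy is below `min_occupancy` (the very beginnings and ends of
#' an alignment), `excluded_no_consensus` when no residue passes the
#' consensus threshold, otherwise `counted` with the consensus residue and
#' its property class.
#'
#' @param cds_set named list of CDS entries, each `list(gene, seq)`.
#' @param msas named list (by cds id) of [build_gene_msa()] results.
#' @param classes property class map from [property_classes()].
#' @param threshold consensus threshold (strict, default 0.5).
#' @param min_occupancy minimum panel occupancy (default 0.5).
#' @return data.frame of stop sites.
#' @export
map_stop_sites <- function(cds_set, msas, classes = property_classes(),
                           threshold = 0.5, min_occupancy = 0.5) {
  rows <- list()
  for (id in names(cds_set)) {
    entry <- cds_set[[id]]
    msa <- msas[[id]]
    if (is.null(msa)) stop("no alignment for CDS '", id, "'")
    q <- query_protein_for_msa(entry$seq)
    for (idx in q$internal_stops) {
      col <- msa$col_of_codon[idx + 1L]
      cc <- column_consensus(msa$panel[, col], threshold = threshold)
      status <-
        if (cc$gap_fraction > 0.5) "excluded_gap"
        else if (cc$occupancy < min_occupancy) "excluded_sparse"
        else if (is.na(cc$aa)) "excluded_no_consensus"
        else "counted"
      rows[[length(rows) + 1L]] <- data.frame(
        cds_id = id, gene = entry$gene, codon = q$codons[idx + 1L],
        codon_index = idx, alignment_column = col,
        consensus_aa = if (status == "counted") cc$aa else NA_character_,
        property_class = if (status == "counted") unname(classes[cc$aa])
                         else NA_character_,
        occupancy = cc$occupancy, gap_fraction = cc$gap_fraction,
        status = status, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(cds_id = character(0), gene = character(0),
                      codon = character(0), codon_index = integer(0),
                      alignment_column = integer(0),
                      consensus_aa = character(0),
                      property_class = character(0), occupancy = numeric(0),
                      gap_fraction = numeric(0), status = character(0)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Tally counted stop sites per codon
#'
#' Aggregates counted sites per stop codon by consensus amino acid and by
#' property class; totals and exclusion counts are preserved so that
#' counted + excluded equals the total number of internal occurrences.
#'
#' @param stop_sites data.frame from [map_stop_sites()].
#' @param classes property class map.
#' @return object of class `stop_tally`: list with `summary` (per codon:
#'   total, counted, excluded_*), `aa_counts` (codon x amino acid matrix) and
#'   `class_counts` (codon x class matrix).
#' @export
tally_stop_sites <- function(stop_sites, classes = property_classes()) {
  codons <- FOCAL_CODONS
  aas <- sort(unique(unname(classes)))
  aa_letters <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  aa_counts <- matrix(0L, nrow = length(codons), ncol = 20L,
                      dimnames = list(codons, aa_letters))
  class_counts <- matrix(0L, nrow = length(codons), ncol = length(aas),
                         dimnames = list(codons, aas))
  summary <- data.frame(
    codon = codons, total = 0L, counted = 0L, excluded_gap = 0L,
    excluded_sparse = 0L, excluded_no_consensus = 0L, row.names = codons)
  if (nrow(stop_sites)) {
    for (cd in codons) {
      ss <- stop_sites[stop_sites$codon == cd, ]
      summary[cd, "total"] <- nrow(ss)
      summary[cd, "counted"] <- sum(ss$status == "counted")
      summary[cd, "excluded_gap"] <- sum(ss$status == "excluded_gap")
      summary[cd, "excluded_sparse"] <- sum(ss$status == "excluded_sparse")
      summary[cd, "excluded_no_consensus"] <-
        sum(ss$status == "excluded_no_consensus")
      cnt <- ss[ss$status == "counted", ]
      if (nrow(cnt)) {
        ta <- table(cnt$consensus_aa)
        aa_counts[cd, names(ta)] <- as.integer(ta)
        tc <- table(cnt$property_class)
        class_counts[cd, names(tc)] <- as.integer(tc)
      }
    }
  }
  structure(list(summary = summary, aa_counts = aa_counts,
                 class_counts = class_counts, classes = classes),
            class = "stop_tally")
}

#' @export
print.stop_tally <- function(x, ...) {
  cat("<stop_tally>\n")
  print(x$summary, row.names = FALSE)
  nz <- colSums(x$aa_counts) > 0
  if (any(nz)) {
    cat("counted consensus residues:\n")
    print(x$aa_counts[, nz, drop = FALSE])
  }
  invisible(x)
}

#' Terminal stop-codon usage profile
#'
#' For each CDS, the focal codon nearest the homology-predicted protein end
#' — within the final `window` fraction of the reference protein length —
#' counts as that gene's terminator (a recoded focal codon a little upstream
#' cannot shadow the true terminator at the end). Genes with no focal codon
#' in the window are reported as `none`: they run stop-free into downstream
#' sequence. A CDS much shorter than its reference (a split-gene segment) is
#' profiled against its own length, since its predicted end is its own.
#'
#' @param cds_set named list of CDS entries `list(gene, seq)`.
#' @param ref_lengths named vector of reference protein lengths (aa) per
#'   gene; a CDS's own codon count is used for genes not listed.
#' @param window terminal window as a fraction of the reference length
#'   (default 0.1); 0 counts exact-end terminators only.
#' @return list with `per_gene` (data.frame) and `usage` (named fraction of
#'   genes terminated by each focal codon, plus `none`).
#' @export
terminal_stop_profile <- function(cds_set, ref_lengths = NULL, window = 0.1) {
  rows <- lapply(names(cds_set), function(id) {
    entry <- cds_set[[id]]
    codons <- split_codons(entry$seq)
    n <- length(codons)
    rl <- ref_lengths[[entry$gene]] %||% (n - 1L)
    if (n - 1L < 0.8 * rl) rl <- n - 1L     # partial segment: own end
    cut <- (1 - window) * rl
    idx <- which(codons %in% FOCAL_CODONS) - 1L       # 0-based
    idx <- idx[idx >= cut]
    if (length(idx)) {
      term <- idx[which.max(idx)]
      data.frame(cds_id = id, gene = entry$gene,
                 terminal_codon = codons[term + 1L],
                 codon_index = term,
                 rel_pos = term / rl, stringsAsFactors = FALSE)
    } else {
      data.frame(cds_id = id, gene = entry$gene, terminal_codon = "none",
                 codon_index = NA_integer_, rel_pos = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  per_gene <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  usage <- vapply(c(FOCAL_CODONS, "none"), function(cd)
    mean(per_gene$terminal_codon == cd), numeric(1))
  list(per_gene = per_gene, usage = usage)
}

#' Pairwise stop-codon profile of two readthrough proteins
#'
#' Globally aligns two proteins carrying X placeholders at their stop
#' positions and counts, over the internal stop placeholders of protein A,
#' how many align to a tyrosine/phenylalanine/tryptophan and how many to a
#' hydrophobic residue of protein B; placeholders aligned to gaps are
#' excluded from both counts and reported separately.
#'
#' @param a,b lists with `protein` (placeholder-rendered) and
#'   `internal_stops` (0-based indices), as from internal rendering of a CDS;
#'   a bare DNA CDS string is also accepted.
#' @param hydrophobic hydrophobic residue set.
#' @return list with counts `n_stops`, `aromatic_yfw`, `hydrophobic`,
#'   `gap_excluded`, and the per-site table `sites`.
#' @export
pairwise_stop_profile <- function(a, b, hydrophobic = HYDROPHOBIC_AA) {
  norm <- function(x) if (is.character(x)) query_protein_for_msa(x) else x
  a <- norm(a)
  b <- norm(b)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$protein), Biostrings::AAString(b$protein),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  col_of_a <- which(pa != "-")
  rows <- lapply(a$internal_stops, function(idx) {
    col <- col_of_a[idx + 1L]
    partner <- pb[col]
    data.frame(codon_index = idx, partner = partner,
               is_yfw = partner %in% c("Y", "F", "W"),
               is_hydrophobic = partner %in% hydrophobic,
               is_gap = partner == "-", stringsAsFactors = FALSE)
  })
  sites <- if (length(rows)) do.call(rbind, rows)
           else data.frame(codon_index = integer(0), partner = character(0),
                           is_yfw = logical(0), is_hydrophobic = logical(0),
                           is_gap = logical(0))
  list(n_stops = nrow(sites),
       aromatic_yfw = sum(sites$is_yfw & !sites$is_gap),
       hydrophobic = sum(sites$is_hydrophobic & !sites$is_gap),
       gap_excluded = sum(sites$is_gap),
       sites = sites)
}

#' Call the genetic code from tally and terminal profile
#'
#' Per focal codon: `sense(aa)` when enough internal sites are counted
#' (`min_sites`), the top consensus residue is consistent (`f_sense`), and
#' the codon is rarely a terminator (`< t_stop`); `stop` when internal
#' evidence is absent (`< min_sites`) but terminal usage is high;
#' `dual_role(aa)` when terminal usage is high and at least `min_dual`
#' counted internal sites agree on a residue; otherwise
#' `insufficient_data`. The emitted code overlays the verdicts on
#' translation table 4.
#'
#' @param tally a `stop_tally`.
#' @param terminal_profile result of [terminal_stop_profile()].
#' @param min_sites minimum counted sites for a sense call (default 5).
#' @param f_sense minimum top-residue fraction among counted (default 0.5).
#' @param t_stop terminal-usage fraction above which a codon is considered a
#'   working terminator (default 0.2).
#' @param min_dual minimum counted sites for the sense half of a dual-role
#'   call (default 2).
#' @return list with `call` (data.frame, one row per codon) and `code`
#'   (a `genetic_code`, source "inferred").
#' @export
infer_code <- function(tally, terminal_profile, min_sites = 5L,
                       f_sense = 0.5, t_stop = 0.2, min_dual = 2L) {
  stopifnot(inherits(tally, "stop_tally"))
  usage <- terminal_profile$usage
  rows <- list()
  tab4 <- genetic_code("table4")
  new_tab <- tab4$table
  dual <- character(0)
  for (cd in FOCAL_CODONS) {
    counted <- tally$summary[cd, "counted"]
    total <- tally$summary[cd, "total"]
    term <- unname(usage[cd])
    aa_row <- tally$aa_counts[cd, ]
    top_aa <- if (counted > 0) names(aa_row)[which.max(aa_row)]
              else NA_character_
    top_frac <- if (counted > 0) max(aa_row) / counted else NA_real_
    consistent <- counted > 0 && top_frac >= f_sense
    verdict <- "insufficient_data"
    if (term >= t_stop) {
      if (counted >= min_dual && consistent) verdict <- "dual_role"
      else if (counted < min_sites) verdict <- "stop"
    } else {
      if (counted >= min_sites && consistent) verdict <- "sense"
    }
    if (verdict == "sense") new_tab[cd] <- top_aa
    else if (verdict == "dual_role") {
      new_tab[cd] <- top_aa
      dual <- c(dual, cd)
    } else if (verdict == "stop") new_tab[cd] <- STOP_CHAR
    rows[[cd]] <- data.frame(
      codon = cd, verdict = verdict,
      aa = if (verdict %in% c("sense", "dual_role")) top_aa
           else NA_character_,
      counted = counted, total = total,
      top_aa = top_aa, top_fraction = top_frac,
      terminal_usage = term,
      flag = if (verdict == "insufficient_data") "insufficient_data" else "",
      stringsAsFactors = FALSE)
  }
  call <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  code <- new_genetic_code("inferred", new_tab, dual_role = dual,
                           source = "inferred")
  list(call = call, code = code)
}

#' Run the full stop-codon analysis on a set of coding sequences
#'
#' Builds one query-vs-panel alignment per CDS, maps all internal stop
#' codons, tallies consensus residues, profiles terminal codons, and calls
#' the genetic code.
#'
#' @param cds_set named list of `list(gene, seq)` entries.
#' @param panel `ortho_panel` or named list with per-gene `taxa`.
#' @param classes property class map.
#' @param window terminal window fraction (default 0.1).
#' @param ... parameters passed to [infer_code()].
#' @return list with `msas`, `sites`, `tally`, `terminal`, `call`, `code`.
#' @export
stop_codon_analysis <- function(cds_set, panel, classes = property_classes(),
                                window = 0.1, ...) {
  taxa_sets <- lapply(panel, function(g) g$taxa %||% g)
  msas <- lapply(cds_set, function(entry) {
    taxa <- taxa_sets[[entry$gene]]
    if (is.null(taxa)) stop("gene '", entry$gene, "' missing from panel")
    q <- query_protein_for_msa(entry$seq)
    build_gene_msa(q$protein, taxa)
  })
  sites <- map_stop_sites(cds_set, msas, classes = classes)
  tly <- tally_stop_sites(sites, classes = classes)
  ref_lengths <- lapply(taxa_sets, function(t)
    sum(strsplit(t[[1]], "")[[1]] != "-"))
  term <- terminal_stop_profile(cds_set, ref_lengths = ref_lengths,
                                window = window)
  res <- infer_code(tly, term, ...)
  list(msas = msas, sites = sites, tally = tly, terminal = term,
       call = res$call, code = res$code)
}

#' Build a CDS set from simulation ground truth
#'
#' @param truth a `ground_truth` object.
#' @return named list of `list(gene, seq)` suitable for
#'   [stop_codon_analysis()].
#' @export
truth_cds_set <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  out <- lapply(names(truth$cds), function(id) {
    g <- truth$genes$gene[truth$genes$cds_id == id]
    list(gene = g, seq = truth$cds[[id]])
  })
  stats::setNames(out, names(truth$cds))
}

#' Write the stop-site table to TSV
#' @param sites data.frame from [map_stop_sites()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stop_sites_tsv <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the tally (codon x amino acid and codon x class) to TSV
#' @param tally a `stop_tally`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tally_tsv <- function(tally, path) {
  aa <- as.data.frame(tally$aa_counts)
  aa <- cbind(codon = rownames(aa), section = "amino_acid", aa)
  cl <- as.data.frame(tally$class_counts)
  cl <- cbind(codon = rownames(cl), section = "property_class", cl)
  sm <- cbind(section = "summary", tally$summary)
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(sm, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("", con)
  utils::write.table(aa, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("", con)
  utils::write.table(cl, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a code call to JSON
#' @param result list with `call` and `code` from [infer_code()].
#' @param path optional output path.
#' @return `path` (invisibly) or JSON string.
#' @export
code_call_to_json <- function(result, path = NULL) {
  doc <- list(call = result$call,
              code = jsonlite::fromJSON(code_to_json(result$code)))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' Export a concatenated trimmed protein alignment
#'
#' Concatenates the per-gene query-plus-panel alignments, keeping only
#' columns where the query is present and panel occupancy is at least
#' `min_occupancy`, and writes FASTA (query row first).
#'
#' @param msas named list of [build_gene_msa()] results.
#' @param path output FASTA path.
#' @param query_name name for the query row.
#' @param min_occupancy minimum panel occupancy for a column to be kept.
#' @return `path`, invisibly.
#' @export
export_concat_alignment <- function(msas, path, query_name = "query",
                                    min_occupancy = 0.5) {
  stopifnot(length(msas) >= 1L)
  qrow <- character(0)
  prows <- NULL
  for (msa in msas) {
    occ <- colMeans(msa$panel != "-")
    keep <- msa$query != "-" & occ >= min_occupancy
    qrow <- c(qrow, msa$query[keep])
    prows <- if (is.null(prows)) msa$panel[, keep, drop = FALSE]
             else cbind(prows, msa$panel[, keep, drop = FALSE])
  }
  seqs <- c(stats::setNames(paste(qrow, collapse = ""), query_name),
            stats::setNames(apply(prows, 1L, paste, collapse = ""),
                            rownames(prows)))
  write_fasta(seqs, path)
}
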