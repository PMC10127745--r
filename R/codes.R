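# Genetic-code representation, translation with stop-readthrough policies, and
# ORF finding under arbitrary codes. A code is a plain list with a 64-entry
# codon -> amino-acid table ("*" marks a terminator), an optional set of
# dual-role codons (sense internally, terminator at CDS ends), and a source
# tag ("preset" or "inferred").

STOP_CHAR <- "*"

all_codons <- function() {
  b <- DNA_BASES
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

#' Construct a genetic code object
#'
#' @param name short label.
#' @param table named character vector mapping all 64 DNA codons to a
#'   one-letter amino acid or `"*"` (terminator).
#' @param dual_role character vector of codons that are sense internally but
#'   terminate translation at the end of a coding sequence. Each must map to
#'   a sense amino acid in `table`.
#' @param source `"preset"` or `"inferred"`.
#' @return an object of class `genetic_code`.
#' @export
new_genetic_code <- function(name, table, dual_role = character(0),
                             source = "preset") {
  code <- structure(
    list(name = as.character(name),
         table = table,
         dual_role = sort(unique(toupper(dual_role))),
         source = match.arg(source, c("preset", "inferred"))),
    class = "genetic_code")
  validate_genetic_code(code)
  code
}

#' Validate a genetic code object
#'
#' Checks the three structural invariants: exactly 64 codon keys with valid
#' amino-acid (or `"*"`) values; at least one terminator (a `"*"` codon or a
#' dual-role codon); dual-role codons map to sense amino acids.
#'
#' @param code a `genetic_code`.
#' @return `code`, invisibly; errors otherwise.
#' @export
validate_genetic_code <- function(code) {
  if (!inherits(code, "genetic_code")) stop("not a genetic_code object")
  tab <- code$table
  if (length(tab) != 64L || !setequal(names(tab), all_codons()))
    stop("genetic code table must have exactly the 64 DNA codons as keys")
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!all(tab %in% c(aas, STOP_CHAR)))
    stop("genetic code values must be one of the 20 amino acids or '*'")
  if (!any(tab == STOP_CHAR) && length(code$dual_role) == 0L)
    stop("a genetic code needs at least one terminator ('*' codon or dual-role codon)")
  bad <- code$dual_role[tab[code$dual_role] == STOP_CHAR |
                          !code$dual_role %in% names(tab)]
  if (length(bad))
    stop("dual-role codons must map to sense amino acids: ", paste(bad, collapse = ", "))
  invisible(code)
}

#' Preset and derived genetic codes
#'
#' `"standard"` is the standard nuclear code; `"table4"` is the mold/protozoan
#' mitochondrial code in which TGA encodes tryptophan (the usual baseline for
#' protist mitogenomes); `"radiolarian"` is table 4 with all three standard
#' stop codons reassigned: TGA = W, TAG = Y, and TAA = Y internally while
#' still acting as the terminator (dual role).
#'
#' @param name one of `"standard"`, `"table4"`, `"radiolarian"`.
#' @return a `genetic_code`.
#' @export
genetic_code <- function(name = c("table4", "standard", "radiolarian")) {
  name <- match.arg(name)
  std <- Biostrings::getGeneticCode("1")
  tab <- stats::setNames(as.character(std), names(std))
  if (name == "standard")
    return(new_genetic_code("standard", tab))
  tab["TGA"] <- "W"
  if (name == "table4")
    return(new_genetic_code("table4", tab))
  tab["TAG"] <- "Y"
  tab["TAA"] <- "Y"
  new_genetic_code("radiolarian", tab, dual_role = "TAA")
}

#' @export
print.genetic_code <- function(x, ...) {
  stops <- names(x$table)[x$table == STOP_CHAR]
  cat(sprintf("<genetic_code '%s' (%s)>\n", x$name, x$source))
  cat("  terminators:", if (length(stops)) paste(stops, collapse = ", ") else "none", "\n")
  if (length(x$dual_role)) {
    dr <- sprintf("%s (=%s internally)", x$dual_role, x$table[x$dual_role])
    cat("  dual-role:", paste(dr, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a genetic code to JSON
#' @param code a `genetic_code`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
code_to_json <- function(code, path = NULL) {
  validate_genetic_code(code)
  doc <- list(name = code$name, source = code$source,
              table = as.list(code$table), dual_role = code$dual_role)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' Deserialize a genetic code from JSON
#' @param x a file path or JSON string produced by [code_to_json()].
#' @return a `genetic_code`.
#' @export
code_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x)
  new_genetic_code(doc$name, unlist(doc$table), as.character(unlist(doc$dual_role)),
                   source = doc$source %||% "preset")
}

#' Construct a coding-sequence record
#'
#' Coordinates are 0-based half-open on the forward strand of the contig;
#' `seq` is always the sense (coding) strand.
#'
#' @param gene gene symbol (e.g. `"cox1"`).
#' @param seq DNA string (A/C/G/T/N), length divisible by 3.
#' @param contig_id contig identifier.
#' @param start,end 0-based half-open nucleotide coordinates.
#' @param strand `"+"` or `"-"`.
#' @param frame_offset 0..2.
#' @return an object of class `cds_record`.
#' @export
cds_record <- function(gene, seq, contig_id = NA_character_,
                       start = 0L, end = nchar(seq), strand = "+",
                       frame_offset = 0L) {
  seq <- toupper(seq)
  assert_dna(seq)
  if (grepl("[^ACGTN]", seq)) stop("CDS '", gene, "': seq may contain only A,C,G,T,N")
  if ((end - start) != nchar(seq))
    stop("CDS '", gene, "': (end - start) must equal sequence length")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(gene = gene, seq = seq, contig_id = contig_id,
                 start = as.integer(start), end = as.integer(end),
                 strand = strand, frame_offset = as.integer(frame_offset)),
            class = "cds_record")
}

#' Translate a coding sequence under a genetic code
#'
#' Returns the protein and the ordered 0-based codon indices of every in-frame
#' stop-codon occurrence (codons whose table value is `"*"` or that are
#' dual-role). The readthrough policy controls what is translated:
#' \describe{
#'   \item{`none`}{translation terminates at the first terminator or
#'     dual-role codon; nothing beyond it is translated.}
#'   \item{`dual_role_internal`}{dual-role codons are read as their sense
#'     amino acid except a terminal occurrence, which terminates; `"*"`
#'     codons still terminate.}
#'   \item{`all_stops_as_X`}{nothing terminates: `"*"` codons are rendered as
#'     `X` and dual-role codons as their sense amino acid, so stop positions
#'     occupy protein coordinates (used to build alignments).}
#' }
#' Codons containing N translate to `X` and are never recorded as stops.
#'
#' @param cds a [cds_record()] or a bare DNA string.
#' @param code a `genetic_code`.
#' @param readthrough readthrough policy (see Details).
#' @return list with `protein` (string) and `stops` (integer vector of
#'   0-based codon indices).
#' @export
translate_cds <- function(cds, code,
                          readthrough = c("none", "dual_role_internal",
                                          "all_stops_as_X")) {
  readthrough <- match.arg(readthrough)
  validate_genetic_code(code)
  seq <- if (inherits(cds, "cds_record")) cds$seq else toupper(cds)
  gene <- if (inherits(cds, "cds_record")) cds$gene else "<anonymous>"
  if (nchar(seq) < 3L) stop("CDS '", gene, "': sequence shorter than one codon")
  if (nchar(seq) %% 3L != 0L)
    stop("CDS '", gene, "': length not divisible by 3")
  codons <- split_codons(seq)
  n <- length(codons)
  aa <- unname(code$table[codons])
  has_n <- grepl("N", codons, fixed = TRUE)
  aa[has_n] <- "X"
  is_term <- !has_n & codons %in% names(code$table)[code$table == STOP_CHAR]
  is_dual <- !has_n & codons %in% code$dual_role
  stops <- which(is_term | is_dual) - 1L   # 0-based

  if (readthrough == "all_stops_as_X") {
    aa[is_term] <- "X"
    return(list(protein = paste(aa, collapse = ""), stops = stops))
  }
  terminators <- if (readthrough == "none") which(is_term | is_dual)
                 else which(is_term | (is_dual & seq_len(n) == n))
  end <- if (length(terminators)) min(terminators) - 1L else n
  list(protein = paste(aa[seq_len(end)], collapse = ""), stops = stops)
}

# Six-frame translation table for a DNA string: one row per frame with the
# protein (all stops rendered as X so local alignments can cross them) and the
# mapping information needed to convert aa coordinates back to forward-strand
# nucleotide coordinates.
six_frames <- function(seq, code) {
  assert_dna(seq)
  n <- nchar(seq)
  rc <- revcomp(seq)
  out <- vector("list", 6L)
  k <- 1L
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    for (off in 0:2) {
      len <- ((n - off) %/% 3L) * 3L
      prot <- if (len >= 3L)
        translate_cds(substr(s, off + 1L, off + len), code,
                      readthrough = "all_stops_as_X")$protein
      else ""
      out[[k]] <- list(strand = strand, offset = off, protein = prot)
      k <- k + 1L
    }
  }
  out
}

# Convert an aa interval [aa_start, aa_end] (1-based, inclusive) in a given
# frame back to 0-based half-open forward-strand nucleotide coordinates.
frame_to_forward <- function(aa_start, aa_end, offset, strand, seqlen) {
  s <- offset + (aa_start - 1L) * 3L        # 0-based on the translated strand
  e <- offset + aa_end * 3L
  if (strand == "+") c(start = s, end = e)
  else c(start = seqlen - e, end = seqlen - s)
}

#' Find open reading frames under an arbitrary genetic code
#'
#' ORFs are maximal stop-to-stop spans of sense codons on all six frames;
#' only terminator (`"*"`) codons delimit ORFs — dual-role codons are sense
#' internally and do not break a span. Coordinates are 0-based half-open on
#' the forward strand.
#'
#' @param seq DNA string.
#' @param code a `genetic_code`.
#' @param min_aa minimum ORF length in codons (>= 1).
#' @return data.frame with columns start, end, frame (0..2), strand, n_aa.
#' @export
find_orfs <- function(seq, code, min_aa = 30L) {
  stopifnot(min_aa >= 1L)
  validate_genetic_code(code)
  if (is.null(seq) || !nzchar(seq))
    return(data.frame(start = integer(0), end = integer(0), frame = integer(0),
                      strand = character(0), n_aa = integer(0)))
  seq <- toupper(seq)
  n <- nchar(seq)
  stops_tab <- names(code$table)[code$table == STOP_CHAR]
  res <- list()
  rc <- revcomp(seq)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    for (off in 0:2) {
      ncod <- (n - off) %/% 3L
      if (ncod < 1L) next
      codons <- substring(s, off + 1L + 3L * (seq_len(ncod) - 1L),
                          off + 3L * seq_len(ncod))
      is_stop <- codons %in% stops_tab
      r <- rle(!is_stop)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values & r$lengths >= min_aa
      for (i in which(keep)) {
        coords <- frame_to_forward(starts[i], ends[i], off, strand, n)
        res[[length(res) + 1L]] <- data.frame(
          start = coords[["start"]], end = coords[["end"]],
          frame = off, strand = strand, n_aa = r$lengths[i])
      }
    }
  }
  if (!length(res))
    return(data.frame(start = integer(0), end = integer(0), frame = integer(0),
                      strand = character(0), n_aa = integer(0)))
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$end, out$strand, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Synonymous codon sets of a code: list mapping each amino acid to the codons
# that encode it. exclude: codons never to use (e.g. focal stop codons).
synonymous_codons <- function(code, exclude = character(0)) {
  tab <- code$table[!names(code$table) %in% exclude]
  split(names(tab), unname(tab))
}

#' Back-translate a protein under a genetic code
#'
#' Chooses among synonymous codons at random with weights favouring an
#' AT-rich third position (weight proportional to the base composition
#' implied by `gc`), optionally excluding specific codons entirely.
#'
#' @param protein amino-acid string (no gaps).
#' @param code a `genetic_code`.
#' @param gc target base GC fraction used to weight codon choice.
#' @param exclude codons never to emit.
#' @return DNA string of length `3 * nchar(protein)`.
#' @export
back_translate <- function(protein, code, gc = 0.25, exclude = character(0)) {
  syn <- synonymous_codons(code, exclude = exclude)
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  missing_aa <- setdiff(unique(aa), names(syn))
  if (length(missing_aa))
    stop("no codon available for amino acid(s): ", paste(missing_aa, collapse = ", "))
  pbase <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  codon_w <- function(codon) prod(pbase[strsplit(codon, "")[[1]]])
  w <- lapply(syn, function(cods) {
    wt <- vapply(cods, codon_w, numeric(1))
    wt / sum(wt)
  })
  cods <- vapply(aa, function(a) {
    cs <- syn[[a]]
    if (length(cs) == 1L) cs else sample(cs, 1L, prob = w[[a]])
  }, character(1))
  paste(cods, collapse = "")
}
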