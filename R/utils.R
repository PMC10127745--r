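# Internal string/sequence helpers. Sequences are plain upper-case character
# strings throughout the package; Biostrings objects appear only at the IO and
# alignment boundaries.

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param seq a single DNA string (A/C/G/T/N).
#' @return the reverse complement, as a character string.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' GC fraction of a sequence
#'
#' Computed as (G+C)/(A+C+G+T); N and other ambiguity characters are ignored
#' in both numerator and denominator.
#'
#' @param seq a single DNA string.
#' @return numeric in \[0, 1\]; NaN for a sequence with no unambiguous base.
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  counts <- table(strsplit(toupper(seq), "", fixed = TRUE)[[1]])
  acgt <- sum(counts[intersect(names(counts), DNA_BASES)])
  gc <- sum(counts[intersect(names(counts), c("G", "C"))])
  as.numeric(gc) / as.numeric(acgt)
}

# Split a DNA string into its in-frame codons (drops a trailing partial codon).
split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# Hamming distance between two equal-length strings.
str_mismatches <- function(a, b) {
  if (identical(a, b)) return(0L)
  sum(charToRaw(a) != charToRaw(b))
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p[DNA_BASES]), collapse = "")
}

# Lexicographically smallest rotation over both strands; canonical form used
# to compare circular sequences.
canonical_rotation <- function(seq) {
  best_rot <- function(s) {
    n <- nchar(s)
    d <- paste0(s, s)
    rots <- substring(d, seq_len(n), seq_len(n) + n - 1L)
    min(rots)
  }
  min(best_rot(seq), best_rot(revcomp(seq)))
}

#' Test whether two sequences are the same circular molecule
#'
#' Equality up to rotation and strand.
#'
#' @param a,b DNA strings.
#' @return logical.
#' @export
same_circular_sequence <- function(a, b) {
  nchar(a) == nchar(b) && canonical_rotation(a) == canonical_rotation(b)
}

#' Read a FASTA file into a named character vector
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA (wrapped at 60 columns)
#' @param seqs named character vector.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#' @param path file path.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write reads to FASTQ with uniform qualities
#' @param reads named character vector.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::PhredQuality(vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), character(1)))
  xq <- Biostrings::QualityScaledDNAStringSet(x, q)
  Biostrings::writeQualityScaledXStringSet(xq, path)
  invisible(path)
}

# Shared check for a non-empty single DNA string argument.
assert_dna <- function(seq, what = "seq") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(sprintf("'%s' must be a single DNA string", what), call. = FALSE)
  invisible(TRUE)
}
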