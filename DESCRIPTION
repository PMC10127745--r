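Package: retmito
Title: Recovery and Genetic Code Inference for Retarian Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to recover small organellar genomes from single-cell read
    sets by iterative bait-and-extend read mapping with coverage/GC contig
    classification, to annotate protein-coding genes, split genes, pseudogene
    fragments, ~50-bp pseudorepeat families and single-nucleotide frameshifts
    by translated homology, and to infer noncanonical mitochondrial genetic
    codes (stop-codon reassignment, including dual-role terminators) by
    mapping in-frame stop codons onto reference orthologue alignments and
    tallying 50-percent-consensus residues. Includes a synthetic-data
    generator that emulates a recoded, AT-rich circular mitogenome with full
    ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
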