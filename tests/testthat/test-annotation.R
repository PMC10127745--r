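# Homology annotation, split genes, pseudogene fragments, pseudorepeats,
# frameshift repair, coding summary.

rad <- genetic_code("radiolarian")

test_that("annotation recovers planted genes with tight boundaries", {
  cfg <- small_cfg(seed = 51)
  pan <- simulate_panel(cfg)
  sim <- simulate_query_genome(cfg, pan)
  ann <- annotate_by_homology(sim$contigs[["mito1"]], pan, rad,
                              contig_id = "mito1")
  tr <- sim$truth$genes
  fs_id <- sim$truth$frameshift$cds_id
  for (i in seq_len(nrow(tr))) {
    r <- tr[i, ]
    hit <- ann[ann$gene == r$gene & ann$start < r$end & ann$end > r$start, ]
    expect_gt(nrow(hit), 0)
    if (r$cds_id == fs_id) next  # boundary truncated at the frameshift
    expect_lte(min(abs(hit$start - r$start)), 15)
    expect_lte(min(abs(hit$end - r$end)), 15)
  }
  expect_equal(nrow(annotate_by_homology("", pan, rad)), 0L)
})

test_that("a 30% gene fragment is a candidate, not a full gene", {
  cfg <- small_cfg(seed = 53)
  pan <- simulate_panel(cfg)
  set.seed(53)
  frag_prot <- substr(panel_consensus_prot(pan$nad9), 1, 36)  # 30% of 120 aa
  frag <- back_translate(frag_prot, rad, gc = 0.25,
                         exclude = c("TGA", "TAG", "TAA"))
  contig <- paste0(random_spacer(400), frag, random_spacer(400))
  ann <- annotate_by_homology(contig, pan["nad9"], rad)
  expect_gt(nrow(ann), 0)
  expect_true(all(ann$type == "gene_fragment_candidate"))
  expect_lt(max(ann$coverage_of_reference), 0.6)
})

test_that("split genes are flagged as complementary parts in order", {
  cfg <- small_cfg(seed = 55)
  pan <- simulate_panel(cfg)
  sim <- simulate_query_genome(cfg, pan)
  rl <- vapply(pan, function(x) nchar(x$taxa[[1]]), integer(1))
  ann <- annotate_by_homology(sim$contigs[["mito1"]], pan, rad,
                              contig_id = "mito1")
  ann <- detect_split_genes(ann, ref_lengths = rl)
  parts <- ann[!is.na(ann$split_part), ]
  expect_equal(sort(unique(parts$gene)), cfg$split_gene)
  expect_setequal(parts$split_part, c("1", "2"))
  # part 1 precedes part 2 on the reference
  p1 <- parts[parts$split_part == "1", ]
  p2 <- parts[parts$split_part == "2", ]
  expect_lt(p1$ref_start, p2$ref_start)
  # full-length genes stay unflagged
  expect_true(all(is.na(ann$split_part[ann$gene != cfg$split_gene])))
})

test_that("two full-length copies are duplicates, not a split", {
  ann <- data.frame(
    gene = c("cob", "cob"), contig_id = "c", start = c(0L, 2000L),
    end = c(1100L, 3100L), strand = "+", frame = 0L,
    split_part = NA_character_, score = c(900, 880),
    coverage_of_reference = c(0.95, 0.93),
    ref_start = c(1L, 5L), ref_end = c(361L, 358L), type = "gene")
  out <- detect_split_genes(ann, ref_lengths = c(cob = 380L))
  expect_true(all(is.na(out$split_part)))
})

test_that("fragment rule: >=4 distinct taxa annotate, 3 never do", {
  cfg <- small_cfg(seed = 57)
  pan <- simulate_panel(cfg)
  sim <- simulate_query_genome(cfg, pan)
  tr <- sim$truth$fragments
  m <- sim$contigs[["mito1"]]
  # isolate the planted-fragment neighbourhood as one intergenic region
  lo <- max(0L, tr$start[1] - 150L)
  hi <- min(nchar(m), tr$end[1] + 150L)
  region <- substr(m, lo + 1L, hi)
  no_ann <- annotate_by_homology("", pan, rad)
  set.seed(57)
  hits <- scan_intergenic_fragments(region, no_ann, pan, rad,
                                    min_taxa = 4L, contig_id = "r")
  expect_true(tr$gene[1] %in% hits$gene)
  expect_gte(hits$n_supporting_taxa[hits$gene == tr$gene[1]][1], 4L)
  # panel restricted to three taxa for that gene: never annotated
  pan3 <- pan
  pan3[[tr$gene[1]]]$taxa <- pan3[[tr$gene[1]]]$taxa[1:3]
  set.seed(57)
  hits3 <- scan_intergenic_fragments(region, no_ann, pan3[tr$gene[1]], rad,
                                     min_taxa = 4L, contig_id = "r")
  expect_false(tr$gene[1] %in% hits3$gene)
  # monotonicity: a stricter threshold never adds hits
  set.seed(57)
  hits6 <- scan_intergenic_fragments(region, no_ann, pan, rad,
                                     min_taxa = 6L, contig_id = "r")
  key <- function(h) paste(h$gene, h$start)
  expect_true(all(key(hits6) %in% key(hits)))
})

test_that("random intergenic sequence yields no fragment hit", {
  cfg <- small_cfg(seed = 59)
  pan <- simulate_panel(cfg)
  set.seed(59)
  region <- random_spacer(800)
  hits <- scan_intergenic_fragments(region,
                                    annotate_by_homology("", pan, rad),
                                    pan, rad, min_taxa = 4L)
  expect_equal(nrow(hits), 0L)
})

test_that("pseudorepeat families are found with their mismatch structure", {
  set.seed(61)
  unit <- random_spacer(50)
  mutate1 <- function(u, pos) {
    substr(u, pos, pos) <- c(A = "C", C = "G", G = "T", T = "A")[[
      substr(u, pos, pos)]]
    u
  }
  seq1 <- paste0(random_spacer(100), mutate1(unit, 7), random_spacer(80),
                 mutate1(unit, 22), random_spacer(120), mutate1(unit, 40),
                 random_spacer(60))
  fams <- detect_pseudorepeats(seq1)
  expect_equal(length(fams), 1L)
  expect_equal(nrow(fams[[1]]$occurrences), 3L)
  expect_lte(fams[[1]]$max_mismatches_observed, 2L)
  # exact tandem duplication
  seq2 <- paste0(random_spacer(30), unit, unit, random_spacer(30))
  fams2 <- detect_pseudorepeats(seq2)
  expect_equal(length(fams2), 1L)
  expect_equal(fams2[[1]]$max_mismatches_observed, 0L)
  # all-distinct windows: no family
  set.seed(62)
  expect_length(detect_pseudorepeats(random_spacer(200, gc = 0.5)), 0L)
})

test_that("planted repeat units are re-discovered and match brute force", {
  cfg <- small_cfg(seed = 63)
  sim <- simulate_query_genome(cfg, simulate_panel(cfg))
  m <- sim$contigs[["mito1"]]
  fams <- detect_pseudorepeats(m)
  truth <- sim$truth$repeats$occurrences
  found <- do.call(rbind, lapply(fams, `[[`, "occurrences"))
  for (i in seq_len(nrow(truth)))
    expect_true(any(abs(found$start - truth$start[i]) <= 3))
  # brute-force all-pairs confirmation on a planted pair
  sub <- substr(m, truth$start[1] - 20, truth$end[2] + 20)
  pairs <- repeat_scan_oracle(sub, 50, 4)
  expect_gt(length(pairs), 0)
})

test_that("single-insertion frameshift repair is exhaustive and calibrated", {
  cfg <- small_cfg(seed = 65)
  pan <- simulate_panel(cfg)
  sim <- simulate_query_genome(cfg, pan)
  tr <- sim$truth
  fs <- tr$frameshift
  g <- tr$genes[tr$genes$cds_id == fs$cds_id, ]
  region <- substr(sim$contigs[["mito1"]], g$start + 1, g$end)
  ref <- panel_consensus_prot(pan[[fs$gene]])
  calls <- repair_single_insertion_frameshift(region, ref, rad)
  expect_gt(nrow(calls), 0)
  top <- calls[calls$score >= max(calls$score) - 13, ]
  expect_true(fs$codon_index %in% top$codon_index)
  # an intact CDS yields no calls
  intact <- tr$cds[["atp9"]]
  expect_equal(nrow(repair_single_insertion_frameshift(
    intact, panel_consensus_prot(pan$atp9), rad)), 0L)
  # two separated deletions cannot be fixed by one insertion
  seq2 <- tr$cds[["cob"]]
  n <- nchar(seq2)
  p1 <- round(n * 0.3); p2 <- round(n * 0.7)
  broken2 <- paste0(substr(seq2, 1, p1 - 1), substr(seq2, p1 + 1, p2 - 1),
                    substr(seq2, p2 + 1, n))
  expect_equal(nrow(repair_single_insertion_frameshift(
    broken2, panel_consensus_prot(pan$cob), rad)), 0L)
})

test_that("repair equals a per-position rescan on a short region", {
  cfg <- small_cfg(seed = 67)
  pan <- simulate_panel(cfg)
  sim <- simulate_query_genome(cfg, pan)
  tr <- sim$truth
  seqf <- tr$cds[["atp9"]]          # 75 aa: small enough to re-scan
  n <- nchar(seqf)
  del <- round(n * 0.5)
  broken <- paste0(substr(seqf, 1, del - 1), substr(seqf, del + 1, n))
  ref <- panel_consensus_prot(pan$atp9)
  calls <- repair_single_insertion_frameshift(broken, ref, rad)
  oracle <- c()
  for (p in 0:nchar(broken)) {
    cand <- paste0(substr(broken, 1, p), "N", substring(broken, p + 1))
    cand <- substr(cand, 1, (nchar(cand) %/% 3) * 3)
    prot <- translate_cds(cand, rad, "all_stops_as_X")$protein
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(ref), Biostrings::AAString(prot), type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
    cov <- (Biostrings::end(Biostrings::pattern(al)) -
              Biostrings::start(Biostrings::pattern(al)) + 1) / nchar(ref)
    if (cov >= 0.9) oracle <- c(oracle, p)
  }
  expect_setequal(calls$insert_pos, oracle)
})

test_that("coding summary reports fractions and intergenic spans", {
  ann0 <- annotate_by_homology("", list(), rad)
  expect_equal(coding_summary(1000L, ann0)$coding_fraction, 0)
  ann1 <- data.frame(gene = "g", contig_id = "c", start = 0L, end = 300L,
                     strand = "+", frame = 0L, split_part = NA_character_,
                     score = 100, coverage_of_reference = 1,
                     ref_start = 1L, ref_end = 100L, type = "gene")
  expect_equal(coding_summary(300L, ann1)$coding_fraction, 1)
  cfg <- small_cfg(seed = 69)
  pan <- simulate_panel(cfg)
  sim <- simulate_query_genome(cfg, pan)
  ann <- annotate_by_homology(sim$contigs[["mito1"]], pan, rad,
                              contig_id = "mito1")
  cs <- coding_summary(nchar(sim$contigs[["mito1"]]), ann)
  tg <- sim$truth$genes
  truth_frac <- sum(tg$end - tg$start) / nchar(sim$contigs[["mito1"]])
  expect_lt(abs(cs$coding_fraction - truth_frac), 0.02)
})

test_that("GFF3 export writes 1-based features of every class", {
  cfg <- small_cfg(seed = 71)
  pan <- simulate_panel(cfg)
  sim <- simulate_query_genome(cfg, pan)
  ann <- annotate_by_homology(sim$contigs[["mito1"]], pan, rad,
                              contig_id = "mito1")
  reps <- detect_pseudorepeats(sim$contigs[["mito1"]])
  tf <- tempfile(fileext = ".gff3")
  export_gff3(tf,
              c(mito1 = nchar(sim$contigs[["mito1"]])),
              ann = ann, repeats = reps,
              frameshift = list(gene = "cox1", contig_id = "mito1",
                                contig_pos = sim$truth$frameshift$contig_pos),
              repeat_contig = "mito1")
  gr <- rtracklayer::import(tf)
  expect_true(all(c("gene", "repeat_region", "frameshift") %in% gr$type))
  g1 <- ann[1, ]
  hit <- gr[gr$type %in% c("gene", "pseudogene_fragment")][1]
  expect_equal(GenomicRanges::start(hit), g1$start + 1L)   # 1-based
  expect_equal(GenomicRanges::end(hit), g1$end)
})
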