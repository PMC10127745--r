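# Stop-site mapping, column consensus, tallies, terminal profiling,
# pairwise profiles, and the genetic-code call.

test_that("MSA mapping is exact for an identical query", {
  taxa <- c(t1 = "MKLFWYHR", t2 = "MKLFWYHR", t3 = "MKLYWYHR")
  msa <- build_gene_msa("MKLFWYHR", taxa)
  expect_equal(msa$col_of_codon, 1:8)
  expect_equal(dim(msa$panel), c(3L, 8L))
  expect_equal(msa$query, strsplit("MKLFWYHR", "")[[1]])
})

test_that("query insertions map to all-gap panel columns", {
  taxa <- c(t1 = "MKLFWYHRDEILNQ", t2 = "MKLFWYHRDEILNQ",
            t3 = "MKLFWYHRDEILNQ")
  query <- "MKLFWYHRGGGGGGGGGGDEILNQ"   # 10-aa insertion after position 8
  msa <- build_gene_msa(query, taxa)
  ins_cols <- msa$col_of_codon[9:18]
  for (j in ins_cols) expect_true(all(msa$panel[, j] == "-"))
  # flanking residues still map to occupied columns
  expect_true(all(msa$panel[, msa$col_of_codon[1]] != "-"))
  expect_true(all(msa$panel[, msa$col_of_codon[24]] != "-"))
})

test_that("column consensus requires a strict unique majority", {
  expect_equal(column_consensus(c("Y", "Y", "Y", "F"))$aa, "Y")
  expect_true(is.na(column_consensus(c("Y", "Y", "F", "F"))$aa))   # tie
  sparse <- column_consensus(c("Y", rep("-", 9)))
  expect_true(is.na(sparse$aa) || sparse$occupancy < 0.5)
  expect_equal(sparse$occupancy, 0.1)
  # exactly 50% is not enough (strictly greater than)
  expect_true(is.na(column_consensus(c("Y", "Y", "F", "L"))$aa))
})

test_that("map_stop_sites records internal sites and excludes terminators", {
  taxa <- c(t1 = "MWFY", t2 = "MWFY", t3 = "MWFY")
  cds <- list(toy = list(gene = "toy", seq = "ATGTGATTTTAA"))
  msa <- list(toy = build_gene_msa("MXFX", taxa))
  sites <- map_stop_sites(cds, msa)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$codon, "TGA")
  expect_equal(sites$codon_index, 1L)
  expect_equal(sites$consensus_aa, "W")
  expect_equal(sites$status, "counted")
})

test_that("sites in all-gap columns are excluded from tallies", {
  taxa <- c(t1 = "MKFY", t2 = "MKFY", t3 = "MKFY")
  # query has an insertion carrying the stop: panel column is all gaps
  cds <- list(g = list(gene = "g", seq = "ATGAAATGATTTTATTAA"))  # M K * F Y .
  msa <- list(g = build_gene_msa("MKXFY", taxa))
  sites <- map_stop_sites(cds, msa)
  expect_equal(sites$status, "excluded_gap")
  tl <- tally_stop_sites(sites)
  expect_equal(tl$summary["TGA", "total"], 1L)
  expect_equal(tl$summary["TGA", "counted"], 0L)
})

test_that("handcrafted sites tally by residue and property class", {
  sites <- data.frame(
    cds_id = "x", gene = "x", codon = "TGA",
    codon_index = 0:9, alignment_column = 1:10,
    consensus_aa = c(rep("W", 8), rep("L", 2)),
    property_class = c(rep("aromatic", 8), rep("nonpolar", 2)),
    occupancy = 1, gap_fraction = 0, status = "counted")
  tl <- tally_stop_sites(sites)
  expect_equal(tl$aa_counts["TGA", "W"], 8L)
  expect_equal(tl$aa_counts["TGA", "L"], 2L)
  expect_equal(tl$class_counts["TGA", "aromatic"], 8L)
  expect_equal(tl$class_counts["TGA", "nonpolar"], 2L)
  expect_equal(tl$summary["TGA", "counted"], 10L)
  # empty input gives an all-zero table
  tl0 <- tally_stop_sites(sites[0, ])
  expect_true(all(tl0$summary$total == 0))
  expect_true(all(tl0$aa_counts == 0))
})

test_that("tally equals a brute-force recount and conserves totals", {
  for (s in c(5, 23)) {
    cfg <- small_cfg(seed = s)
    pan <- simulate_panel(cfg)
    sim <- simulate_query_genome(cfg, pan)
    cds_set <- truth_cds_set(sim$truth)
    res <- stop_codon_analysis(cds_set, pan)
    want <- tally_oracle(cds_set, res$msas)
    got <- res$tally$summary
    expect_equal(stats::setNames(got$total, got$codon), want$total)
    expect_equal(stats::setNames(got$counted, got$codon), want$counted)
    excl <- got$excluded_gap + got$excluded_sparse +
      got$excluded_no_consensus
    expect_equal(stats::setNames(excl, got$codon), want$excluded)
    expect_true(all(got$counted + excl == got$total))
    for (cd in c("TGA", "TAG", "TAA")) {
      oc <- want$aa_counts[[cd]]
      for (aa in names(oc)[oc > 0])
        expect_equal(res$tally$aa_counts[cd, aa], unname(oc[aa]))
    }
  }
})

test_that("terminal profile counts terminators near the predicted end", {
  mk <- function(gene, prot, term = "TAA") {
    list(gene = gene,
         seq = paste0(back_translate(prot, genetic_code("table4"),
                                     exclude = c("TGA", "TAG", "TAA")),
                      term))
  }
  set.seed(81)
  aas <- strsplit("ACDEFGHIKLMNPQRSTV", "")[[1]]
  prot <- function(n) paste(sample(aas, n, replace = TRUE), collapse = "")
  cds <- list(
    a = mk("a", prot(100)), b = mk("b", prot(100)),
    c = list(gene = "c", seq = back_translate(prot(100),
                                              genetic_code("table4"),
                                              exclude = c("TGA", "TAG", "TAA"))))
  rl <- list(a = 100L, b = 100L, c = 100L)
  tp <- terminal_stop_profile(cds, ref_lengths = rl)
  expect_equal(unname(tp$usage[["TAA"]]), 2 / 3)
  expect_equal(unname(tp$usage[["none"]]), 1 / 3)
  # window 0: only exact-end terminators count
  tp0 <- terminal_stop_profile(cds, ref_lengths = rl, window = 0)
  expect_equal(unname(tp0$usage[["TAA"]]), 2 / 3)
  # a terminator one codon early disappears at window 0
  cds$a$seq <- paste0(substr(cds$a$seq, 1, 294), "TAAGCG")
  tp0b <- terminal_stop_profile(cds, ref_lengths = rl, window = 0)
  expect_equal(unname(tp0b$usage[["TAA"]]), 1 / 3)
})

test_that("every synthetic gene terminated by TAA gives usage 1", {
  cfg <- small_cfg(seed = 83)
  sim <- simulate_query_genome(cfg, simulate_panel(cfg))
  cds_set <- truth_cds_set(sim$truth)
  rl <- lapply(sim$truth$proteins, nchar)
  tp <- terminal_stop_profile(cds_set, ref_lengths = rl)
  expect_equal(unname(tp$usage[["TAA"]]), 1)
})

test_that("pairwise stop profile counts aromatic and hydrophobic partners", {
  a <- list(protein = "ACDEFXGHIKXLMNPXQRSTXVWAY",
            internal_stops = c(5L, 10L, 15L, 20L))
  b <- list(protein = "ACDEFYGHIKFLMNPLQRSTVWAY",  # Y, F, L, (gap)
            internal_stops = integer(0))
  pr <- pairwise_stop_profile(a, b)
  expect_equal(pr$n_stops, 4L)
  expect_equal(pr$aromatic_yfw, 2L)     # Y and F
  expect_equal(pr$hydrophobic, 3L)      # Y, F and L
  expect_equal(pr$gap_excluded, 1L)
  # identical stop-free proteins give all-zero counts
  z <- pairwise_stop_profile(list(protein = "MKLV",
                                  internal_stops = integer(0)),
                             list(protein = "MKLV",
                                  internal_stops = integer(0)))
  expect_equal(z$n_stops, 0L)
})

test_that("code call follows the verdict rules at forced boundaries", {
  mk_tally <- function(counted_tga = 0, w = 0) {
    sites <- if (counted_tga > 0)
      data.frame(cds_id = "x", gene = "x", codon = "TGA",
                 codon_index = seq_len(counted_tga) - 1,
                 alignment_column = seq_len(counted_tga),
                 consensus_aa = rep("W", counted_tga),
                 property_class = "aromatic", occupancy = 1,
                 gap_fraction = 0, status = "counted")
    else map_stop_sites(list(), list())
    tally_stop_sites(sites)
  }
  term_all_taa <- list(usage = c(TGA = 0, TAG = 0, TAA = 1, none = 0))
  # zero internal occurrences + 100% terminal usage -> stop
  res <- infer_code(mk_tally(0), term_all_taa)
  expect_equal(res$call$verdict[res$call$codon == "TAA"], "stop")
  expect_equal(res$code$table[["TAA"]], "*")
  # enough counted sites, no terminal usage -> sense
  res2 <- infer_code(mk_tally(8), term_all_taa)
  expect_equal(res2$call$verdict[res2$call$codon == "TGA"], "sense")
  expect_equal(res2$code$table[["TGA"]], "W")
  # absent evidence on both axes -> insufficient data, never a silent call
  expect_equal(res2$call$verdict[res2$call$codon == "TAG"],
               "insufficient_data")
  expect_equal(res2$code$source, "inferred")
})

test_that("truth recovery and negative control on single replicates", {
  cfg <- sim_config(seed = 85, n_taxa = 12L,
                    genes = c(nad1 = 160L, nad3 = 120L, cox1 = 200L,
                              atp9 = 75L, cob = 250L, cox2 = 150L,
                              nad5 = 300L, nad4 = 250L),
                    panel_only_genes = c(nad9 = 120L),
                    intergenic_len = 200L, n_background = 2L,
                    background_len = 3000L)
  pan <- simulate_panel(cfg)
  sim <- simulate_query_genome(cfg, pan)
  res <- stop_codon_analysis(truth_cds_set(sim$truth), pan)
  v <- stats::setNames(res$call$verdict, res$call$codon)
  expect_equal(unname(v[["TGA"]]), "sense")
  expect_equal(unname(v[["TAG"]]), "sense")
  expect_equal(res$call$aa[res$call$codon == "TGA"], "W")
  # negative control: plain table 4, no planting
  cfgn <- small_cfg(seed = 85, truth_code = genetic_code("table4"),
                    recode_density = 0, internal_taa_rate = 0)
  simn <- simulate_query_genome(cfgn, simulate_panel(cfgn))
  resn <- stop_codon_analysis(truth_cds_set(simn$truth),
                              simulate_panel(cfgn))
  expect_false(any(resn$call$verdict %in% c("sense", "dual_role")))
})

test_that("raising recode density does not decrease counted TGA sites", {
  mean_counted <- function(density) {
    mean(vapply(1:6, function(s) {
      cfg <- small_cfg(seed = 100 + s, recode_density = density)
      sim <- simulate_query_genome(cfg, simulate_panel(cfg))
      res <- stop_codon_analysis(truth_cds_set(sim$truth),
                                 simulate_panel(cfg))
      res$tally$summary["TGA", "counted"]
    }, numeric(1)))
  }
  expect_lte(mean_counted(0.15), mean_counted(0.3))
})

test_that("analysis artefacts serialize: tally TSV, sites TSV, call JSON", {
  cfg <- small_cfg(seed = 87)
  pan <- simulate_panel(cfg)
  sim <- simulate_query_genome(cfg, pan)
  res <- stop_codon_analysis(truth_cds_set(sim$truth), pan)
  td <- tempfile(); dir.create(td)
  write_stop_sites_tsv(res$sites, file.path(td, "sites.tsv"))
  write_tally_tsv(res$tally, file.path(td, "tally.tsv"))
  json <- code_call_to_json(res)
  doc <- jsonlite::fromJSON(json)
  expect_equal(doc$call$codon, c("TGA", "TAG", "TAA"))
  expect_true(file.exists(file.path(td, "sites.tsv")))
  got <- utils::read.delim(file.path(td, "sites.tsv"))
  expect_equal(nrow(got), nrow(res$sites))
  # concatenated alignment export has query plus all panel rows
  fa <- file.path(td, "concat.fasta")
  export_concat_alignment(res$msas, fa)
  seqs <- read_fasta(fa)
  expect_equal(length(seqs), cfg$n_taxa + 1L)
  expect_equal(length(unique(nchar(seqs))), 1L)
})
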