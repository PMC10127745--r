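# Synthetic-data generator: panels, query genomes, reads, ground truth.

test_that("identical configs give byte-identical outputs", {
  cfg <- small_cfg(seed = 3)
  a <- simulate_query_genome(cfg, simulate_panel(cfg))
  b <- simulate_query_genome(cfg, simulate_panel(cfg))
  expect_identical(a$contigs, b$contigs)
  expect_identical(a$truth$planted, b$truth$planted)
  ra <- simulate_reads(cfg, a$contigs, a$circular)
  rb <- simulate_reads(cfg, b$contigs, b$circular)
  expect_identical(ra$r1, rb$r1)
  expect_identical(ra$r2, rb$r2)
})

test_that("zero divergence reproduces the ancestor in every panel taxon", {
  cfg <- small_cfg(seed = 2, divergence = 0)
  pan <- simulate_panel(cfg)
  for (g in names(pan)) {
    anc <- paste(pan[[g]]$ancestor, collapse = "")
    expect_true(all(pan[[g]]$taxa == anc))
  }
})

test_that("mean pairwise identity matches the closed-form model expectation", {
  cfg <- sim_config(seed = 1)
  pan <- simulate_panel(cfg)
  # F81 over 20 states: P(identity at total distance T) =
  # exp(-bT) + (1 - exp(-bT)) * sum(pi^2), b = 1/(1 - sum(pi^2));
  # two-class mixture over conserved / variable site rates
  pi2 <- sum(retmito:::MITO_AA_FREQS^2)
  b <- 1 / (1 - pi2)
  rv <- (1 - cfg$conserved_fraction * cfg$conserved_rate) /
    (1 - cfg$conserved_fraction)
  pid <- function(T) exp(-b * T) + (1 - exp(-b * T)) * pi2
  expected <- cfg$conserved_fraction *
    pid(2 * cfg$divergence * cfg$conserved_rate) +
    (1 - cfg$conserved_fraction) * pid(2 * cfg$divergence * rv)
  g <- pan$cox1
  taxa <- g$taxa[1:10]
  ids <- c()
  for (i in 1:9) for (j in (i + 1):10)
    ids <- c(ids, 1 - str_dist(taxa[[i]], taxa[[j]]) / nchar(taxa[[i]]))
  expect_lt(abs(mean(ids) - expected), 0.03)
})

test_that("conserved-class columns are more identical than variable ones", {
  diffs <- replicate(5, {
    cfg <- small_cfg(seed = sample.int(10000, 1))
    pan <- simulate_panel(cfg)
    g <- pan$cob
    mat <- do.call(rbind, strsplit(unname(g$taxa), ""))
    col_id <- apply(mat, 2, function(col) max(table(col)) / length(col))
    mean(col_id[g$classes == "c"]) - mean(col_id[g$classes == "v"])
  })
  expect_true(all(diffs > 0))
})

test_that("planted CDSs translate back to the evolved query proteins", {
  cfg <- small_cfg(seed = 5)
  sim <- simulate_query_genome(cfg, simulate_panel(cfg))
  tr <- sim$truth
  for (id in names(tr$cds)) {
    prot <- translate_cds(tr$cds[[id]], cfg$truth_code,
                          "dual_role_internal")$protein
    row <- tr$genes[tr$genes$cds_id == id, ]
    full <- tr$proteins[[row$gene]]
    if (is.na(row$part)) {
      expect_identical(prot, full)
    }
  }
  # split parts concatenate to the full protein
  sg <- cfg$split_gene
  p1 <- translate_cds(tr$cds[[paste0(sg, ".1")]], cfg$truth_code,
                      "dual_role_internal")$protein
  p2 <- translate_cds(tr$cds[[paste0(sg, ".2")]], cfg$truth_code,
                      "dual_role_internal")$protein
  expect_identical(paste0(p1, p2), tr$proteins[[sg]])
})

test_that("ground-truth bookkeeping matches an independent rescan of the FASTA", {
  cfg <- sim_config(seed = 7)
  sim <- simulate_query_genome(cfg, simulate_panel(cfg))
  tr <- sim$truth
  m <- sim$contigs[[tr$mito_contigs]]
  # rescan: extract each CDS from the contig and count internal focal codons
  rescan <- list(TGA = 0L, TAG = 0L, TAA = 0L)
  for (i in seq_len(nrow(tr$genes))) {
    r <- tr$genes[i, ]
    if (!is.null(tr$frameshift) && r$cds_id == tr$frameshift$cds_id) next
    sub <- substr(m, r$start + 1, r$end)
    if (r$strand == "-") sub <- revcomp(sub)
    ncod <- nchar(sub) %/% 3
    codons <- substring(sub, 3 * seq_len(ncod) - 2, 3 * seq_len(ncod))
    for (cd in names(rescan))
      rescan[[cd]] <- rescan[[cd]] + sum(codons[-ncod] == cd)
  }
  planted <- tr$planted[tr$planted$cds_id != (tr$frameshift$cds_id %||% ""), ]
  expect_equal(rescan$TGA, sum(planted$codon == "TGA"))
  expect_equal(rescan$TAG, sum(planted$codon == "TAG"))
  expect_equal(rescan$TAA, sum(planted$codon == "TAA"))
})

test_that("mito contig is AT-rich relative to background contigs", {
  cfg <- small_cfg(seed = 9)
  sim <- simulate_query_genome(cfg, simulate_panel(cfg))
  gc_mito <- gc_content(sim$contigs[["mito1"]])
  for (bg in sim$truth$background_contigs)
    expect_lt(gc_mito, gc_content(sim$contigs[[bg]]))
})

test_that("inconsistent planting configs are rejected", {
  expect_error(sim_config(truth_code = genetic_code("standard"),
                          recode_density = 0.3),
               "TGA to STOP")
  expect_error(sim_config(truth_code = genetic_code("table4"),
                          recode_density = 0, internal_taa_rate = 0.02),
               "TAA to STOP")
  expect_error(sim_config(recode_density = 1.2), "\\[0, 1\\]")
  # table 4 with no planting is a valid negative-control config
  expect_s3_class(sim_config(truth_code = genetic_code("table4"),
                             recode_density = 0, internal_taa_rate = 0),
                  "sim_config")
})

test_that("error-free reads are exact substrings and hit target coverage", {
  cfg <- small_cfg(seed = 13)
  sim <- simulate_query_genome(cfg, simulate_panel(cfg))
  reads <- simulate_reads(cfg, sim$contigs, sim$circular)
  m <- sim$contigs[["mito1"]]
  doubled <- paste0(m, m)
  rcd <- revcomp(doubled)
  sel <- grep("^mito1", names(reads$r1))[1:50]
  for (r in c(reads$r1[sel], reads$r2[sel]))
    expect_true(grepl(r, doubled, fixed = TRUE) ||
                  grepl(r, rcd, fixed = TRUE))
  # alignment-free coverage estimates within 15% of target
  mito_reads <- c(reads$r1[grep("^mito1", names(reads$r1))],
                  reads$r2[grep("^mito1", names(reads$r2))])
  cov <- kmer_coverage(m, mito_reads)
  expect_lt(abs(cov - cfg$coverage_mito) / cfg$coverage_mito, 0.15)
  bg_reads <- c(reads$r1[grep("^bg1", names(reads$r1))],
                reads$r2[grep("^bg1", names(reads$r2))])
  covb <- kmer_coverage(sim$contigs[["bg1"]], bg_reads)
  expect_lt(abs(covb - cfg$coverage_background) / cfg$coverage_background,
            0.15)
})

test_that("reads span the origin of a circular contig", {
  cfg <- small_cfg(seed = 17)
  sim <- simulate_query_genome(cfg, simulate_panel(cfg))
  reads <- simulate_reads(cfg, sim$contigs, sim$circular)
  org <- reads$origin
  L <- nchar(sim$contigs[["mito1"]])
  spanning <- org$contig_id == "mito1" & org$start > L - cfg$insert
  expect_gt(sum(spanning), 0)
  # a contig shorter than the read length is skipped with a warning
  expect_warning(simulate_reads(cfg, c(tiny = "ACGTACGT")), "skipped")
})

test_that("ground truth round-trips through JSON", {
  cfg <- small_cfg(seed = 19)
  sim <- simulate_query_genome(cfg, simulate_panel(cfg))
  back <- truth_from_json(truth_to_json(sim$truth))
  expect_identical(back$genes, sim$truth$genes)
  expect_identical(back$planted, sim$truth$planted)
  expect_identical(back$cds, sim$truth$cds)
  expect_identical(back$code$table, sim$truth$code$table)
  expect_identical(back$frameshift$cds_pos, sim$truth$frameshift$cds_pos)
  expect_identical(back$repeats$occurrences$start,
                   sim$truth$repeats$occurrences$start)
})
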