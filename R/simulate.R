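# Synthetic-data generator: reference orthologue panels, a query mitogenome
# written under a chosen (possibly recoded) genetic code with the structural
# quirks seen in retarian mitogenomes (large AT-rich intergenic regions,
# ~50-bp pseudorepeat families, planted pseudogene fragments, a split gene,
# a single-nucleotide frameshift), and paired sequencing reads — all with
# full ground truth so every downstream stage can be tested in isolation.

# AT-rich mitochondrial amino-acid composition used for ancestral proteins.
# Enriched in residues with AT-rich codons (F, I, K, N, Y, L), as observed in
# very AT-rich organellar proteomes.
MITO_AA_FREQS <- c(
  A = 0.040, C = 0.015, D = 0.030, E = 0.035, F = 0.085, G = 0.055,
  H = 0.015, I = 0.095, K = 0.070, L = 0.130, M = 0.030, N = 0.065,
  P = 0.035, Q = 0.020, R = 0.025, S = 0.070, T = 0.045, V = 0.060,
  W = 0.025, Y = 0.055)

# Default protein lengths (aa) for the 13 shared mitochondrial protein-coding
# genes, plus nad9 which appears in reference panels (and as a planted
# pseudogene fragment) but not as a full gene in the query genome.
DEFAULT_GENES <- c(
  nad1 = 320L, nad3 = 120L, nad4 = 480L, nad4L = 100L, nad5 = 600L,
  nad7 = 400L, cob = 380L, cox1 = 520L, cox2 = 250L, cox3 = 260L,
  atp1 = 500L, atp6 = 230L, atp9 = 75L)

DEFAULT_PANEL_ONLY_GENES <- c(nad9 = 180L)

FOCAL_CODONS <- c("TGA", "TAG", "TAA")

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic generator. The same config (and
#' seed) always produces byte-identical outputs.
#'
#' @param seed RNG seed (integer).
#' @param n_taxa reference panel size.
#' @param genes named integer vector of gene protein lengths (aa).
#' @param panel_only_genes genes present in the panel but not written into
#'   the query genome (available for pseudogene-fragment planting).
#' @param divergence expected amino-acid substitutions per site separating
#'   each panel taxon (and the query) from the shared ancestor.
#' @param conserved_fraction,conserved_rate two-class site-rate mixture:
#'   a `conserved_fraction` of sites evolve at relative rate
#'   `conserved_rate`; the remaining (variable) sites at the complementary
#'   rate so the mean relative rate is 1.
#' @param truth_code the genetic code the query genome is written under.
#' @param recode_density fraction of eligible (conserved-class) W and Y sites
#'   written as TGA and TAG respectively.
#' @param internal_taa_rate fraction of eligible Y sites written as TAA.
#' @param gc_target GC fraction of intergenic spacers (coding codon choice is
#'   biased toward the same base composition).
#' @param intergenic_len mean intergenic spacer length (nt).
#' @param repeat_spec list(unit_len, copies, max_mismatch) for the planted
#'   pseudorepeat family.
#' @param fragment_spec list of list(gene, fraction) pseudogene fragments to
#'   plant in intergenic regions.
#' @param split_gene gene written as two separate segments (`NULL` for none).
#' @param frameshift_gene gene receiving a single-nucleotide deletion
#'   (`NULL` for none).
#' @param terminal_codon terminator appended to every coding segment; must
#'   terminate under `truth_code`.
#' @param n_background,background_len,background_gc background (non-mito)
#'   contigs emulating nuclear/symbiont sequence.
#' @param read_len,insert,coverage_mito,coverage_background,error_rate
#'   paired-read simulation parameters.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_taxa = 30L,
                       genes = DEFAULT_GENES,
                       panel_only_genes = DEFAULT_PANEL_ONLY_GENES,
                       divergence = 0.5,
                       conserved_fraction = 0.6,
                       conserved_rate = 0.1,
                       truth_code = genetic_code("radiolarian"),
                       recode_density = 0.3,
                       internal_taa_rate = 0.02,
                       gc_target = 0.25,
                       intergenic_len = 500L,
                       repeat_spec = list(unit_len = 50L, copies = 6L,
                                          max_mismatch = 2L),
                       fragment_spec = list(list(gene = "nad9", fraction = 0.4)),
                       split_gene = "nad1",
                       frameshift_gene = "cox1",
                       terminal_codon = "TAA",
                       n_background = 5L,
                       background_len = 10000L,
                       background_gc = 0.45,
                       read_len = 150L,
                       insert = 300L,
                       coverage_mito = 40,
                       coverage_background = 5,
                       error_rate = 0) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  frac01 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop("'", nm, "' must be a single value in [0, 1]")
  }
  frac01(cfg$recode_density, "recode_density")
  frac01(cfg$internal_taa_rate, "internal_taa_rate")
  frac01(cfg$gc_target, "gc_target")
  frac01(cfg$background_gc, "background_gc")
  frac01(cfg$error_rate, "error_rate")
  frac01(cfg$conserved_fraction, "conserved_fraction")
  if (any(cfg$genes <= 0L) || any(cfg$panel_only_genes <= 0L))
    stop("gene lengths must be positive")
  if (cfg$n_taxa < 2L) stop("n_taxa must be >= 2")
  if (cfg$divergence < 0) stop("divergence must be >= 0")
  if (cfg$conserved_rate <= 0 || cfg$conserved_rate > 1)
    stop("conserved_rate must be in (0, 1]")
  validate_genetic_code(cfg$truth_code)
  tab <- cfg$truth_code$table
  terminates <- tab[cfg$terminal_codon] == STOP_CHAR ||
    cfg$terminal_codon %in% cfg$truth_code$dual_role
  if (!isTRUE(terminates))
    stop("terminal_codon '", cfg$terminal_codon,
         "' does not terminate under truth_code")
  if (cfg$recode_density > 0 && tab[["TGA"]] == STOP_CHAR)
    stop("inconsistent truth: recode_density > 0 but truth_code maps TGA to STOP")
  if (cfg$recode_density > 0 && tab[["TAG"]] == STOP_CHAR)
    stop("inconsistent truth: recode_density > 0 but truth_code maps TAG to STOP")
  if (cfg$internal_taa_rate > 0 && tab[["TAA"]] == STOP_CHAR)
    stop("inconsistent truth: internal_taa_rate > 0 but truth_code maps TAA to STOP")
  if (!is.null(cfg$split_gene) && !cfg$split_gene %in% names(cfg$genes))
    stop("split_gene must be one of the query genes")
  if (!is.null(cfg$frameshift_gene) && !cfg$frameshift_gene %in% names(cfg$genes))
    stop("frameshift_gene must be one of the query genes")
  if (cfg$read_len < 10L || cfg$insert < cfg$read_len)
    stop("need read_len >= 10 and insert >= read_len")
  if (cfg$coverage_mito <= cfg$coverage_background)
    stop("coverage_mito must exceed coverage_background")
  invisible(cfg)
}

# F81-style amino-acid replacement over 20 states with stationary frequencies
# pi: after time t a site keeps its state with probability exp(-beta*t) and
# otherwise redraws from pi; beta normalises to one expected substitution per
# unit time.
f81_beta <- function(pi) 1 / (1 - sum(pi^2))

evolve_protein <- function(anc, classes, divergence, conserved_rate,
                           variable_rate, pi = MITO_AA_FREQS) {
  beta <- f81_beta(pi)
  rate <- ifelse(classes == "c", conserved_rate, variable_rate)
  keep <- stats::runif(length(anc)) < exp(-beta * divergence * rate)
  out <- anc
  redraw <- which(!keep)
  if (length(redraw))
    out[redraw] <- sample(names(pi), length(redraw), replace = TRUE, prob = pi)
  out
}

variable_rate <- function(cfg)
  (1 - cfg$conserved_fraction * cfg$conserved_rate) / (1 - cfg$conserved_fraction)

#' Simulate a reference orthologue panel
#'
#' For each gene, draws an ancestral protein from an AT-rich mitochondrial
#' amino-acid composition, assigns each site to a conserved or variable rate
#' class, and evolves `n_taxa` independent tips (star phylogeny) under an
#' F81-style replacement process at the configured divergence. Tips are
#' gap-free and mutually aligned by construction.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `ortho_panel`: per gene, a list with
#'   `ancestor` and `query` site vectors omitted (`ancestor` chars,
#'   `classes` "c"/"v", and `taxa`, a named character vector of proteins).
#' @export
simulate_panel <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  rv <- variable_rate(cfg)
  all_genes <- c(cfg$genes, cfg$panel_only_genes)
  taxa_ids <- sprintf("t%02d", seq_len(cfg$n_taxa))
  panel <- lapply(names(all_genes), function(g) {
    L <- all_genes[[g]]
    anc <- sample(names(MITO_AA_FREQS), L, replace = TRUE, prob = MITO_AA_FREQS)
    classes <- ifelse(stats::runif(L) < cfg$conserved_fraction, "c", "v")
    taxa <- vapply(taxa_ids, function(t)
      paste(evolve_protein(anc, classes, cfg$divergence, cfg$conserved_rate, rv),
            collapse = ""), character(1))
    list(ancestor = anc, classes = classes, taxa = taxa)
  })
  names(panel) <- names(all_genes)
  structure(panel, class = "ortho_panel",
            model = list(type = "F81-20state",
                         pi = MITO_AA_FREQS,
                         divergence = cfg$divergence,
                         conserved_fraction = cfg$conserved_fraction,
                         conserved_rate = cfg$conserved_rate,
                         variable_rate = rv))
}

# Plant focal codons genome-wide. `units` is a list of per-CDS lists with
# elements codons, aa, classes; eligible sites are conserved-class W/Y sites
# pooled across all units, and the planted count per codon is the rounded
# expected count (exact-count planting). Returns list(units, planted df).
plant_focal_codons <- function(units, cfg) {
  site_tab <- do.call(rbind, lapply(names(units), function(id) {
    u <- units[[id]]
    data.frame(cds_id = id, pos = seq_along(u$aa), aa = u$aa,
               cons = u$classes == "c", stringsAsFactors = FALSE)
  }))
  elig_w <- which(site_tab$aa == "W" & site_tab$cons)
  elig_y <- which(site_tab$aa == "Y" & site_tab$cons)
  pick <- function(pool, n) {
    n <- min(n, length(pool))
    if (n > 0L) sample(pool, n) else integer(0)
  }
  n_of <- function(rate, n) if (rate <= 0 || n == 0L) 0L else ceiling(rate * n)
  i_tga <- pick(elig_w, n_of(cfg$recode_density, length(elig_w)))
  i_tag <- pick(elig_y, n_of(cfg$recode_density, length(elig_y)))
  i_taa <- pick(setdiff(elig_y, i_tag),
                n_of(cfg$internal_taa_rate, length(elig_y)))
  sel <- rbind(
    if (length(i_tga)) cbind(site_tab[i_tga, ], codon = "TGA"),
    if (length(i_tag)) cbind(site_tab[i_tag, ], codon = "TAG"),
    if (length(i_taa)) cbind(site_tab[i_taa, ], codon = "TAA"))
  planted <- data.frame(cds_id = character(0), gene = character(0),
                        codon = character(0), codon_index = integer(0),
                        true_aa = character(0), stringsAsFactors = FALSE)
  if (!is.null(sel) && nrow(sel)) {
    for (i in seq_len(nrow(sel)))
      units[[sel$cds_id[i]]]$codons[sel$pos[i]] <- sel$codon[i]
    planted <- data.frame(cds_id = sel$cds_id,
                          gene = vapply(units[sel$cds_id], `[[`, "", "gene"),
                          codon = sel$codon, codon_index = sel$pos - 1L,
                          true_aa = sel$aa, stringsAsFactors = FALSE)
    planted <- planted[order(planted$cds_id, planted$codon_index), ]
    rownames(planted) <- NULL
  }
  list(units = units, planted = planted)
}

# Mutate a repeat unit with exactly k substitutions.
mutate_unit <- function(unit, k) {
  if (k == 0L) return(unit)
  chars <- strsplit(unit, "", fixed = TRUE)[[1]]
  pos <- sample(length(chars), k)
  for (p in pos) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  paste(chars, collapse = "")
}

#' Simulate the query mitogenome and background contigs
#'
#' Evolves a query tip from each panel ancestor, back-translates it under the
#' truth code (never emitting TGA/TAG/TAA except where explicitly planted),
#' plants recoded codons at conserved W/Y sites, splits one gene in two,
#' deletes one nucleotide from one gene, and assembles a circular mito contig
#' with AT-rich intergenic spacers carrying a pseudorepeat family and
#' pseudogene fragments, plus higher-GC background contigs.
#'
#' @param cfg a [sim_config()].
#' @param panel the matching [simulate_panel()] output.
#' @return list with `contigs` (named character), `circular` (named logical)
#'   and `truth` (class `ground_truth`).
#' @export
simulate_query_genome <- function(cfg, panel) {
  validate_sim_config(cfg)
  stopifnot(inherits(panel, "ortho_panel"))
  set.seed(cfg$seed + 1L)
  rv <- variable_rate(cfg)

  # --- query proteins and CDS units -------------------------------------
  units <- list()     # per CDS segment: id, gene, part, aa, classes, codons
  proteins <- list()
  for (g in names(cfg$genes)) {
    pg <- panel[[g]]
    qaa <- evolve_protein(pg$ancestor, pg$classes, cfg$divergence,
                          cfg$conserved_rate, rv)
    proteins[[g]] <- paste(qaa, collapse = "")
    if (!is.null(cfg$split_gene) && g == cfg$split_gene) {
      k <- round(length(qaa) * stats::runif(1, 0.4, 0.6))
      segs <- list(`1` = seq_len(k), `2` = (k + 1L):length(qaa))
    } else {
      segs <- list(none = seq_along(qaa))
    }
    for (part in names(segs)) {
      idx <- segs[[part]]
      cds_id <- if (part == "none") g else paste0(g, ".", part)
      aa <- qaa[idx]
      codons <- split_codons(back_translate(paste(aa, collapse = ""),
                                            cfg$truth_code, gc = cfg$gc_target,
                                            exclude = FOCAL_CODONS))
      units[[cds_id]] <- list(id = cds_id, gene = g,
                              part = if (part == "none") NA_character_ else part,
                              aa = aa, classes = pg$classes[idx],
                              codons = codons)
    }
  }
  pl <- plant_focal_codons(units, cfg)
  units <- pl$units
  planted <- pl$planted
  for (id in names(units))
    units[[id]]$seq <- paste(c(units[[id]]$codons, cfg$terminal_codon),
                             collapse = "")

  # --- frameshift: delete one nucleotide from one gene's genome copy ------
  frameshift <- NULL
  if (!is.null(cfg$frameshift_gene)) {
    fid <- cfg$frameshift_gene
    intact <- units[[fid]]$seq
    n <- nchar(intact)
    # deletion in the central 60% of the CDS, away from the terminator
    del <- sample(seq(round(0.2 * n), round(0.8 * n)), 1L)
    units[[fid]]$write_seq <- paste0(substr(intact, 1L, del - 1L),
                                     substr(intact, del + 1L, n))
    frameshift <- list(cds_id = fid, gene = fid,
                       cds_pos = del - 1L,                  # 0-based, intact CDS
                       codon_index = (del - 1L) %/% 3L)
  }

  # --- intergenic spacers with repeats and fragments ---------------------
  n_units <- length(units)
  spacer_len <- as.integer(
    pmax(cfg$repeat_spec$unit_len + 20L,
         round(stats::runif(n_units, 0.7, 1.3) * cfg$intergenic_len)))
  spacers <- vapply(spacer_len, random_dna, character(1), gc = cfg$gc_target)

  repeat_unit <- random_dna(cfg$repeat_spec$unit_len, gc = cfg$gc_target)
  rep_local <- data.frame(spacer = integer(0), start = integer(0),
                          mismatches = integer(0))
  host <- sample(rep(seq_len(n_units), length.out = cfg$repeat_spec$copies))
  for (s in host) {
    ulen <- cfg$repeat_spec$unit_len
    taken <- rep_local$start[rep_local$spacer == s]
    cand <- setdiff(seq_len(spacer_len[s] - ulen + 1L),
                    unlist(lapply(taken, function(t) (t - ulen + 1L):(t + ulen - 1L))))
    if (!length(cand)) next
    at <- sample(cand, 1L)
    k <- sample(0:cfg$repeat_spec$max_mismatch, 1L)
    substr(spacers[s], at, at + ulen - 1L) <- mutate_unit(repeat_unit, k)
    rep_local <- rbind(rep_local,
                       data.frame(spacer = s, start = at, mismatches = k))
  }

  frag_local <- list()
  frag_spacers <- setdiff(seq_len(n_units), unique(rep_local$spacer))
  for (fs in cfg$fragment_spec) {
    pg <- panel[[fs$gene]]
    if (is.null(pg)) stop("fragment gene '", fs$gene, "' not in panel")
    qaa <- evolve_protein(pg$ancestor, pg$classes, cfg$divergence,
                          cfg$conserved_rate, rv)
    flen <- max(10L, round(fs$fraction * length(qaa)))
    fstart <- sample(length(qaa) - flen + 1L, 1L)
    fseq <- back_translate(paste(qaa[fstart:(fstart + flen - 1L)], collapse = ""),
                           cfg$truth_code, gc = cfg$gc_target,
                           exclude = FOCAL_CODONS)
    strand <- sample(c("+", "-"), 1L)
    wseq <- if (strand == "+") fseq else revcomp(fseq)
    ok <- frag_spacers[spacer_len[frag_spacers] >= nchar(wseq) + 2L]
    if (!length(ok)) {  # grow a spacer to fit
      s <- frag_spacers[1]
      spacers[s] <- paste0(spacers[s],
                           random_dna(nchar(wseq) + 2L - spacer_len[s],
                                      gc = cfg$gc_target))
      spacer_len[s] <- nchar(spacers[s])
      ok <- s
    }
    s <- if (length(ok) == 1L) ok else sample(ok, 1L)
    at <- sample(spacer_len[s] - nchar(wseq) + 1L, 1L)
    substr(spacers[s], at, at + nchar(wseq) - 1L) <- wseq
    frag_local[[length(frag_local) + 1L]] <-
      data.frame(gene = fs$gene, spacer = s, start = at, len = nchar(wseq),
                 strand = strand, fraction = fs$fraction)
    frag_spacers <- setdiff(frag_spacers, s)
  }

  # --- assemble the circular mito contig ---------------------------------
  order_units <- sample(names(units))
  strands <- stats::setNames(sample(c("+", "-"), n_units, replace = TRUE),
                             order_units)
  if (!is.null(cfg$frameshift_gene)) strands[cfg$frameshift_gene] <- "+"
  mito_id <- "mito1"
  pieces <- character(0)
  cursor <- 0L
  genes_df <- list()
  spacer_offset <- integer(n_units)
  for (i in seq_len(n_units)) {
    spacer_offset[i] <- cursor
    pieces <- c(pieces, spacers[i])
    cursor <- cursor + spacer_len[i]
    uid <- order_units[i]
    u <- units[[uid]]
    sseq <- u$write_seq %||% u$seq
    wseq <- if (strands[uid] == "+") sseq else revcomp(sseq)
    genes_df[[uid]] <- data.frame(
      cds_id = uid, gene = u$gene, part = u$part, contig_id = mito_id,
      start = cursor, end = cursor + nchar(wseq), strand = strands[uid],
      stringsAsFactors = FALSE)
    pieces <- c(pieces, wseq)
    cursor <- cursor + nchar(wseq)
  }
  mito <- paste(pieces, collapse = "")
  genes_df <- do.call(rbind, c(genes_df, list(make.row.names = FALSE)))

  if (!is.null(frameshift)) {
    gs <- genes_df[genes_df$cds_id == frameshift$cds_id, ]
    frameshift$contig_id <- mito_id
    frameshift$contig_pos <- gs$start + frameshift$cds_pos   # "+" strand only
  }

  # spacer-local coordinates -> contig coordinates (0-based half-open)
  repeats <- NULL
  if (nrow(rep_local)) {
    st <- spacer_offset[rep_local$spacer] + rep_local$start - 1L
    repeats <- list(unit = repeat_unit,
                    occurrences = data.frame(
                      contig_id = mito_id, start = st,
                      end = st + cfg$repeat_spec$unit_len,
                      mismatches = rep_local$mismatches))
  }
  fragments <- if (length(frag_local)) {
    fl <- do.call(rbind, frag_local)
    data.frame(gene = fl$gene, contig_id = mito_id,
               start = spacer_offset[fl$spacer] + fl$start - 1L,
               end = spacer_offset[fl$spacer] + fl$start - 1L + fl$len,
               strand = fl$strand, fraction = fl$fraction,
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(0), contig_id = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               fraction = numeric(0))
  }

  # --- background contigs ------------------------------------------------
  bg_ids <- if (cfg$n_background > 0L) sprintf("bg%d", seq_len(cfg$n_background))
            else character(0)
  bg <- stats::setNames(
    vapply(seq_along(bg_ids), function(i)
      random_dna(cfg$background_len, gc = cfg$background_gc), character(1)),
    bg_ids)

  contigs <- c(stats::setNames(mito, mito_id), bg)
  circular <- stats::setNames(c(TRUE, rep(FALSE, length(bg_ids))),
                              c(mito_id, bg_ids))

  truth <- structure(list(
    code = cfg$truth_code,
    mito_contigs = mito_id,
    background_contigs = bg_ids,
    contig_lengths = vapply(contigs, nchar, integer(1)),
    genes = genes_df,
    cds = stats::setNames(lapply(units, `[[`, "seq"), names(units)),
    proteins = proteins,
    planted = planted,
    fragments = fragments,
    repeats = repeats,
    frameshift = frameshift,
    model = attr(panel, "model")), class = "ground_truth")

  list(contigs = contigs, circular = circular, truth = truth)
}

#' Simulate paired reads from contigs
#'
#' Uniform-start error-prone paired reads at a per-contig target coverage.
#' Circular contigs are sampled across the origin. A contig shorter than the
#' read length is skipped with a warning.
#'
#' @param cfg a [sim_config()].
#' @param contigs named character vector of contig sequences.
#' @param circular named logical (default: all linear).
#' @param coverage named numeric target coverage per contig; defaults to
#'   `coverage_mito` for contigs named in `mito_contigs` and
#'   `coverage_background` otherwise.
#' @param mito_contigs ids treated as mitochondrial for the default coverage.
#' @return list with `r1`, `r2` (named character vectors; names share a pair
#'   id) and `origin` (data.frame with the true source of each pair).
#' @export
simulate_reads <- function(cfg, contigs, circular = NULL, coverage = NULL,
                           mito_contigs = "mito1") {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 2L)
  if (is.null(circular))
    circular <- stats::setNames(rep(FALSE, length(contigs)), names(contigs))
  if (is.null(coverage))
    coverage <- stats::setNames(
      ifelse(names(contigs) %in% mito_contigs,
             cfg$coverage_mito, cfg$coverage_background),
      names(contigs))
  r1 <- r2 <- character(0)
  origin <- list()
  add_errors <- function(read) {
    if (cfg$error_rate == 0) return(read)
    chars <- strsplit(read, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(chars)) < cfg$error_rate)
    for (p in hit) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
    paste(chars, collapse = "")
  }
  for (cid in names(contigs)) {
    L <- nchar(contigs[[cid]])
    if (cfg$read_len > L) {
      warning("contig '", cid, "' shorter than read length; skipped")
      next
    }
    ins <- min(cfg$insert, L)
    n_pairs <- max(1L, round(coverage[[cid]] * L / (2 * cfg$read_len)))
    if (circular[[cid]]) {
      src <- paste0(contigs[[cid]], substr(contigs[[cid]], 1L, ins))
      starts <- sample.int(L, n_pairs, replace = TRUE)
    } else {
      src <- contigs[[cid]]
      starts <- sample.int(L - ins + 1L, n_pairs, replace = TRUE)
    }
    frag <- substring(src, starts, starts + ins - 1L)
    flip <- stats::runif(n_pairs) < 0.5
    frag[flip] <- vapply(frag[flip], revcomp, character(1), USE.NAMES = FALSE)
    a <- substr(frag, 1L, cfg$read_len)
    b <- vapply(substring(frag, ins - cfg$read_len + 1L, ins), revcomp,
                character(1), USE.NAMES = FALSE)
    if (cfg$error_rate > 0) {
      a <- vapply(a, add_errors, character(1), USE.NAMES = FALSE)
      b <- vapply(b, add_errors, character(1), USE.NAMES = FALSE)
    }
    ids <- sprintf("%s_p%06d", cid, seq_len(n_pairs))
    r1 <- c(r1, stats::setNames(a, ids))
    r2 <- c(r2, stats::setNames(b, ids))
    origin[[cid]] <- data.frame(pair_id = ids, contig_id = cid,
                                start = starts - 1L, flipped = flip)
  }
  list(r1 = r1, r2 = r2,
       origin = do.call(rbind, c(origin, list(make.row.names = FALSE))))
}

#' Serialize ground truth to JSON
#' @param truth a `ground_truth` object.
#' @param path optional output file.
#' @return `path` (invisibly) or a JSON string.
#' @export
truth_to_json <- function(truth, path = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  doc <- unclass(truth)
  doc$code <- list(name = truth$code$name, source = truth$code$source,
                   table = as.list(truth$code$table),
                   dual_role = truth$code$dual_role)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' Deserialize ground truth from JSON
#' @param x file path or JSON string from [truth_to_json()].
#' @return a `ground_truth` object.
#' @export
truth_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x, simplifyDataFrame = TRUE)
  doc$code <- new_genetic_code(doc$code$name, unlist(doc$code$table),
                               as.character(unlist(doc$code$dual_role)),
                               source = doc$code$source)
  doc$cds <- lapply(doc$cds, as.character)
  doc$proteins <- lapply(doc$proteins, as.character)
  doc$contig_lengths <- vapply(doc$contig_lengths, as.integer, integer(1))
  int_cols <- function(df, cols) {
    for (cc in intersect(cols, names(df))) df[[cc]] <- as.integer(df[[cc]])
    df
  }
  doc$genes <- int_cols(as.data.frame(doc$genes), c("start", "end"))
  doc$planted <- int_cols(as.data.frame(doc$planted), "codon_index")
  doc$fragments <- int_cols(as.data.frame(doc$fragments), c("start", "end"))
  if (!is.null(doc$repeats))
    doc$repeats$occurrences <-
      int_cols(as.data.frame(doc$repeats$occurrences),
               c("start", "end", "mismatches"))
  if (!is.null(doc$frameshift))
    doc$frameshift[c("cds_pos", "codon_index", "contig_pos")] <-
      lapply(doc$frameshift[c("cds_pos", "codon_index", "contig_pos")],
             as.integer)
  structure(doc, class = "ground_truth")
}
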