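# End-to-end orchestration: recovery -> annotation -> code inference, with
# standard-format outputs (FASTA, GFF3, TSV, JSON) and a machine-readable
# report carrying per-stage provenance.

#' Extract an in-frame coding sequence from an annotation
#'
#' Returns the sense-strand CDS implied by a homology annotation: trimmed to
#' codon boundaries, extended downstream up to `slack` nt so the terminator
#' (which homology cannot align) is included, and cut at the first focal
#' codon within `end_margin` codons of the reference protein end, so the
#' terminator closes the CDS and downstream intergenic sequence never enters
#' it.
#'
#' @param contig contig sequence.
#' @param ann_row one annotation row (start/end 0-based half-open, strand).
#' @param ref_len reference protein length (aa) for the end cut.
#' @param slack maximum downstream extension (nt).
#' @param end_margin codon tolerance of the end cut, absorbing annotation
#'   boundary error (default 5).
#' @return DNA string, length divisible by 3.
#' @export
extract_cds_from_annotation <- function(contig, ann_row, ref_len = NULL,
                                        slack = 45L, end_margin = 5L) {
  L <- nchar(contig)
  if (ann_row$strand == "+") {
    s <- ann_row$start
    e <- min(L, ann_row$end + slack)
    seq <- substr(contig, s + 1L, e)
  } else {
    s <- max(0L, ann_row$start - slack)
    e <- ann_row$end
    seq <- revcomp(substr(contig, s + 1L, e))
  }
  seq <- substr(seq, 1L, (nchar(seq) %/% 3L) * 3L)
  codons <- split_codons(seq)
  if (!is.null(ref_len)) {
    cut <- ref_len - end_margin
    focal <- which(codons %in% FOCAL_CODONS) - 1L
    focal <- focal[focal >= cut]
    if (length(focal))
      seq <- substr(seq, 1L, (focal[1] + 1L) * 3L)
  }
  seq
}

#' Run the full recovery / annotation / inference pipeline
#'
#' Stages run in order `recover` (coverage/GC statistics, homology seeding,
#' blob classification, optional bait-and-extend when reads are supplied),
#' `annotate` (gene annotation, split-gene detection, intergenic fragment
#' scan, pseudorepeat families, frameshift repair) and `infer` (stop-codon
#' analysis and code call). Any stage can be skipped. All outputs are
#' written under `out_dir` and summarised in `report.json`.
#'
#' @param contigs named character vector of contig sequences (nonempty).
#' @param panel `ortho_panel` or named list with per-gene `taxa`.
#' @param reads optional character vector of reads for coverage statistics
#'   and bait-and-extend finishing.
#' @param code baseline genetic code for translation (default table 4).
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed controlling every stochastic step (null score
#'   calibration).
#' @param stages subset of c("recover", "annotate", "infer").
#' @param min_score annotation score threshold.
#' @param min_taxa fragment-rule support threshold.
#' @param scan_fragments run the intergenic fragment scan (slowest step).
#' @param species label used in the presence matrix.
#' @param ... further parameters passed to [infer_code()].
#' @return list with the stage results and the report (also written to
#'   `report.json`).
#' @export
run_pipeline <- function(contigs, panel, reads = NULL,
                         code = genetic_code("table4"),
                         out_dir = ".", seed = 1L,
                         stages = c("recover", "annotate", "infer"),
                         min_score = 100, min_taxa = 4L,
                         scan_fragments = TRUE, species = "query", ...) {
  if (length(contigs) == 0L || any(!nzchar(contigs)))
    stop("pipeline input validation: empty contig input")
  if (is.null(names(contigs)))
    stop("pipeline input validation: contigs must be named")
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  taxa_sets <- lapply(panel, function(g) g$taxa %||% g)
  ref_lengths <- lapply(taxa_sets, function(t)
    sum(strsplit(t[[1]], "")[[1]] != "-"))
  report <- list(seed = seed,
                 input = list(
                   n_contigs = length(contigs),
                   contig_ids = names(contigs),
                   contig_md5 = unname(vapply(contigs, function(s) {
                     tf <- tempfile()
                     on.exit(unlink(tf))
                     writeLines(s, tf)
                     unname(tools::md5sum(tf))
                   }, character(1)))))

  mito_ids <- names(contigs)
  blob <- NULL
  assembly <- NULL
  if ("recover" %in% stages) {
    seeds_df <- seed_mito_contigs(contigs, panel, code, min_score = min_score)
    seed_ids <- attr(seeds_df, "seeds")
    if (!is.null(reads) && length(reads)) {
      stats <- contig_stats(contigs, reads)
      if (length(seed_ids)) {
        blob <- blob_classify(stats, seed_ids)
        mito_ids <- blob$contig_id[blob$label == "mito"]
      } else blob <- cbind(stats, label = "other")
      write_blob_table(blob, file.path(out_dir, "blob.tsv"))
      if (length(seed_ids)) {
        bait <- contigs[[seed_ids[1]]]
        st <- bait_extend_iterate(reads, bait)
        cz <- circularize(st$consensus)
        assembly <- list(consensus = cz$seq, circular = cz$is_circular,
                         rounds = st$round, converged = st$converged,
                         n_recruited = length(st$recruited_read_ids))
        write_fasta(stats::setNames(cz$seq, paste0(
          seed_ids[1], if (cz$is_circular) "_circular" else "_linear")),
          file.path(out_dir, "assembly.fasta"))
      }
    } else {
      mito_ids <- if (length(seed_ids)) seed_ids else character(0)
    }
    report$recover <- list(seeds = seed_ids, mito_contigs = mito_ids,
                           circular = assembly$circular %||% NA,
                           params = list(min_score = min_score))
  }

  ann_all <- NULL
  fragments <- NULL
  repeats <- NULL
  frameshifts <- NULL
  if ("annotate" %in% stages) {
    ann_list <- list()
    for (cid in intersect(mito_ids, names(contigs))) {
      ann <- annotate_by_homology(contigs[[cid]], panel, code,
                                  contig_id = cid, min_score = min_score)
      ann <- detect_split_genes(ann, ref_lengths = unlist(ref_lengths))
      # split parts are genes even when each covers only part of the ref
      ann$type[!is.na(ann$split_part)] <- "gene"
      ann_list[[cid]] <- ann
    }
    ann_all <- do.call(rbind, c(ann_list, list(make.row.names = FALSE)))
    if (scan_fragments) {
      frg <- list()
      for (cid in names(ann_list)) {
        ann <- ann_list[[cid]]
        frg[[cid]] <- scan_intergenic_fragments(
          contigs[[cid]], ann[ann$type == "gene", , drop = FALSE], panel,
          code, min_taxa = min_taxa, contig_id = cid)
      }
      fragments <- do.call(rbind, c(frg, list(make.row.names = FALSE)))
    }
    repeats <- list()
    for (cid in names(ann_list))
      repeats[[cid]] <- detect_pseudorepeats(contigs[[cid]])
    # frameshift repair on truncated full genes
    frameshifts <- list()
    if (!is.null(ann_all) && nrow(ann_all)) {
      trunc <- ann_all[is.na(ann_all$split_part) &
                         ann_all$coverage_of_reference >= 0.3 &
                         ann_all$coverage_of_reference < 0.9, , drop = FALSE]
      for (i in seq_len(nrow(trunc))) {
        a <- trunc[i, ]
        rl <- ref_lengths[[a$gene]]
        L <- nchar(contigs[[a$contig_id]])
        # When the hit starts deep into the reference it is the gene's tail
        # downstream of the suspected deletion: project back to the gene
        # start, one base short of the naive projection (the deleted base),
        # so the upstream half sits in frame 0 of the region.
        tail_hit <- a$ref_start - 1L > 0.2 * rl
        # one deleted base upstream makes the genomic span 3*aa - 1
        up_nt <- if (tail_hit) (a$ref_start - 1L + 10L) * 3L - 1L else 0L
        if (a$strand == "+") {
          rs <- a$start - up_nt
          while (rs < 0L) rs <- rs + 3L        # clamp, preserving frame
          re <- min(L, rs + rl * 3L + 60L)
          region <- substr(contigs[[a$contig_id]], rs + 1L, re)
          region_start <- rs
        } else {
          re <- a$end + up_nt
          while (re > L) re <- re - 3L
          rs <- max(0L, re - rl * 3L - 60L)
          region <- revcomp(substr(contigs[[a$contig_id]], rs + 1L, re))
          region_start <- rs
        }
        calls <- repair_single_insertion_frameshift(
          region, panel_consensus(taxa_sets[[a$gene]]), code)
        if (!nrow(calls))    # suspected readthrough: focal codons can't veto
          calls <- repair_single_insertion_frameshift(
            region, panel_consensus(taxa_sets[[a$gene]]), code,
            require_stop_free = FALSE)
        if (nrow(calls))
          frameshifts[[length(frameshifts) + 1L]] <- list(
            gene = a$gene, contig_id = a$contig_id, strand = a$strand,
            region_start = region_start,
            contig_pos = if (a$strand == "+")
                           region_start + calls$insert_pos[1]
                         else re - calls$insert_pos[1],
            calls = calls, region = region)
      }
    }
    gff <- file.path(out_dir, "annotations.gff3")
    export_gff3(gff,
                stats::setNames(vapply(contigs, nchar, integer(1)),
                                names(contigs)),
                ann = ann_all, fragments = fragments,
                repeats = if (length(repeats)) repeats[[1]] else NULL,
                frameshift = if (length(frameshifts))
                  frameshifts[[1]][c("gene", "contig_id", "contig_pos")]
                  else NULL,
                repeat_contig = names(repeats)[1])
    pres <- presence_matrix(
      stats::setNames(list(ann_all), species),
      genes = names(taxa_sets),
      fragments_by_species = stats::setNames(list(fragments), species))
    utils::write.table(pres, file.path(out_dir, "presence.tsv"), sep = "\t",
                       quote = FALSE)
    report$annotate <- list(
      n_genes = if (is.null(ann_all)) 0L else sum(ann_all$type == "gene"),
      split_genes = if (is.null(ann_all)) character(0)
                    else unique(ann_all$gene[!is.na(ann_all$split_part)]),
      n_fragments = if (is.null(fragments)) NA_integer_ else nrow(fragments),
      n_repeat_families = if (length(repeats)) length(repeats[[1]]) else 0L,
      frameshift_genes = vapply(frameshifts, `[[`, "", "gene"),
      params = list(min_score = min_score, min_taxa = min_taxa))
  }

  inference <- NULL
  if ("infer" %in% stages) {
    cds_set <- list()
    if (is.null(ann_all) || !nrow(ann_all))
      stop("inference stage needs annotations (run 'annotate' or supply them)")
    fs_genes <- vapply(frameshifts %||% list(), `[[`, "", "gene")
    # a successfully repaired gene is a full gene even if its uncorrected
    # annotation covered only part of the reference
    ann_all$type[ann_all$gene %in% fs_genes & is.na(ann_all$split_part)] <-
      "gene"
    genes_tab <- ann_all[ann_all$type == "gene", , drop = FALSE]
    for (i in seq_len(nrow(genes_tab))) {
      a <- genes_tab[i, ]
      id <- if (is.na(a$split_part)) a$gene
            else paste0(a$gene, ".", a$split_part)
      if (a$gene %in% fs_genes) {
        fs <- frameshifts[[match(a$gene, fs_genes)]]
        p <- fs$calls$insert_pos[1]
        seq <- paste0(substr(fs$region, 1L, p), "N",
                      substring(fs$region, p + 1L))
        seq <- extract_cds_from_annotation(
          seq, list(start = 0L, end = nchar(seq), strand = "+"),
          ref_len = ref_lengths[[a$gene]], slack = 0L)
      } else {
        rl <- if (is.na(a$split_part)) ref_lengths[[a$gene]]
              else a$ref_end - a$ref_start + 1L    # part: its own end
        seq <- extract_cds_from_annotation(contigs[[a$contig_id]], a,
                                           ref_len = rl)
      }
      cds_set[[id]] <- list(gene = a$gene, seq = seq)
    }
    inference <- stop_codon_analysis(cds_set, panel, ...)
    write_stop_sites_tsv(inference$sites, file.path(out_dir, "stop_sites.tsv"))
    write_tally_tsv(inference$tally, file.path(out_dir, "stop_tally.tsv"))
    code_call_to_json(inference, file.path(out_dir, "code_call.json"))
    code_to_json(inference$code, file.path(out_dir, "inferred_code.json"))
    export_concat_alignment(inference$msas,
                            file.path(out_dir, "concat_alignment.fasta"))
    report$infer <- list(
      verdicts = stats::setNames(inference$call$verdict,
                                 inference$call$codon),
      aa = stats::setNames(inference$call$aa, inference$call$codon),
      n_sites = sum(inference$tally$summary$total),
      n_counted = sum(inference$tally$summary$counted))
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  list(report = report, blob = blob, assembly = assembly,
       annotations = ann_all, fragments = fragments, repeats = repeats,
       frameshifts = frameshifts, inference = inference)
}

#' Gene presence/absence/fragment matrix across species
#'
#' Rows are genes, columns species; cells are `present` (full gene
#' annotated), `fragment` (only a partial annotation or an intergenic
#' fragment hit), or `absent`.
#'
#' @param ann_by_species named list (species) of annotation data.frames.
#' @param genes character vector of genes to report (default: union seen).
#' @param fragments_by_species optional named list of fragment-hit tables.
#' @return character matrix genes x species.
#' @export
presence_matrix <- function(ann_by_species, genes = NULL,
                            fragments_by_species = NULL) {
  stopifnot(length(ann_by_species) >= 1L)
  if (is.null(genes))
    genes <- sort(unique(unlist(c(
      lapply(ann_by_species, function(a) a$gene),
      lapply(fragments_by_species %||% list(), function(f) f$gene)))))
  out <- matrix("absent", nrow = length(genes),
                ncol = length(ann_by_species),
                dimnames = list(genes, names(ann_by_species)))
  for (sp in names(ann_by_species)) {
    ann <- ann_by_species[[sp]]
    frg <- (fragments_by_species %||% list())[[sp]]
    for (g in genes) {
      full <- !is.null(ann) && nrow(ann) &&
        any(ann$gene == g & ann$type == "gene")
      part <- (!is.null(ann) && nrow(ann) &&
                 any(ann$gene == g & ann$type == "gene_fragment_candidate")) ||
        (!is.null(frg) && nrow(frg) && any(frg$gene == g))
      out[g, sp] <- if (full) "present" else if (part) "fragment" else "absent"
    }
  }
  out
}
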