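---
title: "Methods: recovering organellar genomes and inferring noncanonical genetic codes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recovering organellar genomes and inferring noncanonical genetic codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Single-cell sequencing of uncultured protists (here: Foraminifera and
Radiolaria, the rhizarian superphylum Retaria) yields a mixed bag of
contigs: host nuclear fragments, symbiont genomes, bacteria — and, because
organellar genomes exist in many copies per cell, heavily over-represented
mitochondrial sequence. `retmito` implements the computational path from
such an assembly to an annotated mitogenome and, where the genome uses a
noncanonical genetic code, to an inferred codon table:

1. **Recovery** — identify mitochondrial contigs by translated homology
   against a reference protein panel, corroborate by coverage/GC ("blob")
   statistics, and finish the molecule by iterative bait-and-extend read
   mapping with circularity detection.
2. **Annotation** — locate the protein-coding genes, flag genes split into
   two segments, find pseudogene fragments in the large intergenic regions
   (a hit requires at least four distinct supporting panel taxa), detect
   ~50-bp pseudorepeat families, and repair single-nucleotide frameshifts.
3. **Code inference** — map every in-frame TGA/TAG/TAA of the coding
   sequences onto columns of query-versus-panel protein alignments, tally
   the >50% consensus residues at those columns, profile which codon
   terminates each gene, and call each focal codon sense, stop, or
   dual-role.

A synthetic-data generator produces all of the above conditions with full
ground truth, so every stage is testable without any external download.

# The genetic-code model

A genetic code is a plain 64-entry table from DNA codons to amino acids,
with `*` marking terminators, plus a set of *dual-role* codons: codons read
as an amino acid internally but as a terminator at the end of a coding
sequence. Three presets ship: the standard code; translation table 4 (TGA =
W), the usual baseline for protist mitochondria; and the "radiolarian" code
built from table 4 by reassigning TAG to Y and TAA to Y with
`dual_role = {TAA}`. Translation supports three readthrough policies:
`none` (any terminator or dual-role codon ends translation),
`dual_role_internal` (dual-role codons are sense except at the CDS end),
and `all_stops_as_X` (nothing terminates; terminators become `X`
placeholders so stop positions keep protein coordinates — this is how
query proteins enter alignments, deliberately avoiding any bias toward a
candidate amino acid).

ORF finding is stop-to-stop: maximal spans of sense codons on all six
frames. Dual-role codons do not delimit ORFs (they are sense internally),
which has the correct consequence that in a fully recoded genome ORF
structure is uninformative and homology must drive annotation. Start-codon
choice is deliberately not modelled; ATG-anchored ORFs are a stricter
subset the user can derive.

# The synthetic generator: what it emulates, and what it does not

`sim_config()` fixes the study conditions; the defaults are the conditions
under which the acceptance properties are evaluated.

**Reference panels.** For each of the 13 shared mitochondrial genes (plus
nad9, which appears only in panels and as a plantable pseudogene fragment;
lengths 75–600 aa, realistic per gene), an ancestral protein is drawn from
an AT-rich mitochondrial amino-acid composition (F, I, K, N, Y, L
enriched — the composition that very AT-rich organellar genomes encode).
Thirty panel taxa evolve independently from the ancestor (a star
phylogeny: the inference treats panel taxa exchangeably) under an
F81-style 20-state replacement process — a site keeps its residue with
probability `exp(-beta*t)` and otherwise redraws from the stationary
frequencies, with `beta` normalising to one expected substitution per unit
time. Expected pairwise identity therefore has the closed form
`exp(-b*T) + (1 - exp(-b*T)) * sum(pi^2)` at total separation `T`, which
the test suite uses as its oracle. Site rates follow a two-class mixture:
a fraction 0.6 of sites are *conserved* (relative rate 0.1 — strongly
constrained positions, the columns on which a consensus-based tally can
work at all) and the rest are *variable* (rate chosen so the mean is 1).
At the default divergence of 0.5 substitutions/site this yields panels
whose conserved columns carry a clear majority residue and whose variable
columns mostly do not — the same contrast the real analysis depends on.

**The query genome.** A query tip evolves from each ancestor at the same
divergence and is back-translated under the truth code with codon choice
weighted toward an AT-rich third position (GC target 0.25; the link
between extreme AT richness and code change is the reason this matters).
Three conventions deserve emphasis:

* *Focal codons appear only where planted.* TGA, TAG and TAA are excluded
  from ordinary synonymous choice and written only by the recoding
  machinery or as terminators. This makes the ground truth an exact
  enumeration of internal focal codons, and it makes the negative control
  meaningful: under plain table 4, TGA is a genuine sense codon (W), and a
  generator that used it freely would produce genomes where a sense(W)
  call for TGA is *correct* — no longer a negative control of the
  inference.
* *Eligible sites are conserved-class W/Y sites.* `recode_density` (0.3)
  of eligible W sites become TGA, and of eligible Y sites become TAG;
  `internal_taa_rate` (0.02) of eligible Y sites become TAA. Planting at
  conserved sites means every planted codon is informative for the
  consensus tally. Real data differ here: the study organisms show many
  in-frame TAAs at *non*-consensus columns (divergent gene tails), which
  this generator does not emulate — passing tests demonstrate recovery of
  a detectable signal, not robustness to the full messiness of real
  alignments.
* *Exact-count planting.* The number planted is `ceiling(rate * n_eligible)`
  with positions sampled without replacement, rather than independent
  coin-flips per site. With ~130 eligible Y sites a 2% rate plants only
  2–3 TAAs; Bernoulli planting would leave a substantial fraction of
  genomes with fewer than the two counted sites the dual-role verdict
  minimally requires, making "did the generator plant a detectable
  condition" a coin toss. Exact counts keep the planted condition stable
  given a seed.

Each coding segment ends with the truth terminator (TAA). One gene (nad1)
is split into two separately terminated segments at 40–60% of its length;
one gene (cox1) loses one nucleotide at a uniformly drawn position in its
central 60%. Intergenic spacers (~500 nt each, GC 0.25) carry a planted
family of six ~50-bp pseudorepeat copies, each up to 2 substitutions from
the family unit, and a 40% fragment of nad9. Background contigs (five of
10 kb, GC 0.45) emulate co-assembled nuclear/symbiont sequence. The mito
contig totals ~20 kb with a coding fraction near 0.65 — intergenic
regions are large, though the real genomes are larger still (46–50 kb
with even lower coding fractions); we keep the simulated molecule at
20 kb so that assembly properties can be evaluated over many replicates.

**Reads.** Uniform-start paired reads (2 × 150 nt, insert 300 nt) at 40×
on the circular mito contig (sampled across the origin) and 5× on
background, with configurable per-base substitution error (default 0 —
the recruitment thresholds below do their discriminating work at the
boundary regardless).

# Recovery

`seed_mito_contigs()` translates each contig in six frames (stops as X)
and Smith–Waterman-aligns each gene's panel consensus against them
(BLOSUM62, gap open 11, extend 1). A contig with any hit at score ≥ 100
is a seed. The threshold is deliberately high: AT-rich DNA translates into
protein-like strings sharing the composition of genuine AT-rich
mitochondrial proteins, and under BLOSUM62 such junk accumulates positive
score; ~100 clears that composition-biased null with a wide margin while
genuine genes score several hundred.

`blob_classify()` labels non-seed contigs mitochondrial iff coverage falls
within a factor-2 band of the median seed coverage *and* GC within ±0.08
of the median seed GC — the two-dimensional signature (order-of-magnitude
coverage excess, markedly lower GC) that separates organellar blobs.

`bait_extend_iterate()` is the finishing step: starting from a seed
sequence, each round recruits every unrecruited read (either orientation)
whose best *ungapped* placement overlaps the consensus by ≥ 100 nt with a
mismatch fraction ≤ 1% (no gaps), then extends both ends by per-column
majority vote over overhanging recruited reads, repeating until no further
reads map. Implementation notes that matter for reproducibility:

* Placement is anchored by exact 24-mers sampled every 12 positions of the
  read, so any mismatch-free stretch of ≥ 47 nt inside the overlap
  guarantees an anchor; candidates are verified by exact mismatch
  counting over the clipped overlap window. Within a round every read is
  evaluated against the same consensus snapshot, making recruitment
  order-independent; majority-vote ties break toward the
  lexicographically smallest base, so output is deterministic.
* The recruited set and the consensus length are monotone across rounds
  by construction; non-convergence within `max_rounds` is reported, never
  silently truncated.

`circularize()` declares the molecule circular iff a suffix of ≥ 50 nt
exactly matches a prefix, and trims one copy of the duplicated terminus.
For comparisons, `same_circular_sequence()` canonicalises by the
lexicographically smallest rotation over both strands.

# Annotation

`annotate_by_homology()` aligns each gene's panel consensus against all
six frame translations; within a frame the best hit is masked and the
frame re-aligned once, so both segments of a split gene are found even
when they share a frame. Two guards address the AT-composition problem:
the score floor above, and *windowed end-trimming* of accepted local
alignments — alignment ends are trimmed back to the outermost 15-column
window with ≥ 40% identity, because compositional junk occasionally
chains onto a genuine hit and would otherwise overstate both the genomic
span and the aligned reference interval. With trimming, planted gene
boundaries are recovered to within ~15 nt.

`detect_split_genes()` flags two same-gene annotations as parts 1/2 when
their reference intervals are complementary: combined coverage ≥ 0.8 of
the reference with mutual overlap ≤ 0.1 — two full-length copies fail the
overlap condition and are reported as duplicates instead.

`scan_intergenic_fragments()` implements the distinct-taxon support rule:
a region from the annotation complement is annotated as a fragment of gene
g iff at least four *distinct panel taxa* (source labels, not alignments —
one taxon with repeated domains cannot satisfy the rule) hit it above
threshold. The threshold is calibrated per run as the 0.99 quantile of
scores of shuffled region translations against panel proteins, floored at
90. Two calibration choices are deliberate: the quantile is 0.99 rather
than 0.95 because with a 30-taxon panel a 5% per-alignment false-hit rate
would let the four-taxon rule fire on random spacers (P(≥4 of 30) ≈ 6%);
and the floor exists because shuffling preserves composition, so on short
regions the empirical null is itself noisy while raw scores below ~90
are never meaningful at these search sizes.

`detect_pseudorepeats()` finds families of ≥ 2 approximately repeated
~50-nt units in which every occurrence lies within 2 substitutions of the
family consensus. Families are anchored on exact shared 14-mers; because a
single occurrence can sit `max_mismatch` away from the consensus in either
direction, the first collection pass searches at twice the bound, builds a
majority consensus, and re-collects against it before verifying the
per-occurrence bound. Occurrences are placed greedily without overlap, and
family boundaries may extend up to 10 nt while all occurrences still
agree.

`repair_single_insertion_frameshift()` exhaustively tries inserting one N
at every position of a region and keeps positions where the repaired
in-frame translation aligns to ≥ 90% of the reference with no terminator
codon inside the aligned span (the N codon reads as X). Two subtleties:

* In a genome suspected of stop-codon readthrough, internal focal codons
  cannot veto a repair — `require_stop_free = FALSE` drops the terminator
  condition, and the pipeline falls back to it automatically when the
  strict form returns nothing.
* The insertion position is resolvable to the codon, not the base:
  within-codon choices are equivalent (the N codon is X regardless), and
  score differences between adjacent codons are bounded by one aligned
  residue — at most 13 under BLOSUM62 (largest diagonal 11 plus the X
  penalty). Calls within 13 of the best score therefore form the *repair
  window*; tests assert the planted position lies in that window, which in
  practice spans one to two codons.

When the uncorrected annotation catches only the gene segment downstream
of the deletion, the pipeline projects back to the expected gene start —
one base short of the naive 3-per-residue projection, because the genome
is missing exactly the deleted base — so the upstream half enters the
repair region in frame.

# Code inference

For each coding sequence the query protein is rendered with X placeholders
at every TGA/TAG/TAA (the codons under test — their status relative to
the standard code is exactly the question) and aligned globally against
the panel consensus; panel rows are then expanded with all-gap columns at
query insertions so each query codon maps to exactly one alignment column.
Aligning a query into an existing reference alignment via its consensus
is a profile-alignment simplification; the `aligner` argument accepts any
function returning the two aligned strings if an external MSA tool is
preferred.

Every *internal* focal codon (a terminal terminator is excluded) becomes a
stop site with a status. The consensus of its column — computed over
panel rows only; the query cannot vote at its own stop — is the unique
most frequent residue among non-gap rows at strictly greater than 50%
frequency (the strict reading; ties are genuinely ambiguous). Sites are
excluded when the column is majority-gap, when panel occupancy falls below
50% (a position-independent reading of "the very beginnings and ends of
the alignment"), or when no residue passes the threshold; conservation
(counted + excluded = total) holds exactly and is asserted against a
brute-force recount. Counted sites aggregate per codon by consensus
residue and by biochemical class — aromatic {F, W, Y, H}, charged
{D, E, K, R}, polar {S, T, N, Q, C}, nonpolar {G, A, V, L, I, P, M};
histidine's placement and every membership are configurable because no
single standard grouping exists. The hydrophobic set used by the pairwise
profile is {A, V, L, I, M, F, W, Y, C}.

`terminal_stop_profile()` asks which focal codon terminates each gene:
the focal codon *nearest* the homology-predicted protein end, within the
final 10% of the reference length (configurable; 0 restricts to the exact
end). Taking the nearest rather than the first codon in the window
matters in a recoded genome, where a sense-recoded TAG a few codons
upstream must not shadow the true terminator. A segment much shorter than
its reference (a split-gene part) is profiled against its own length.
Genes with no focal codon in the window are reported as running stop-free
into downstream sequence — itself a diagnostic the real genomes show.

`infer_code()` combines the two axes per codon, with defaults
`min_sites = 5`, `f_sense = 0.5`, `t_stop = 0.2`, `min_dual = 2`:

* terminal usage below `t_stop` and ≥ `min_sites` counted sites agreeing
  (top residue ≥ `f_sense`) → **sense**(top residue);
* terminal usage ≥ `t_stop` with ≥ `min_dual` agreeing counted sites →
  **dual-role**(top residue);
* terminal usage ≥ `t_stop` with fewer than `min_sites` counted sites →
  **stop**;
* anything else — including high internal counts together with high
  terminal usage but no coherent residue — → **insufficient data**,
  never a silent call.

The emitted code overlays these verdicts on table 4 and is tagged
`source = "inferred"`. On default synthetic conditions this recovers
TGA→W, TAG→Y and the dual-role TAA→Y/stop, and on table-4 negative
controls it calls stop or insufficient-data only. The thresholds are free
parameters: the original determination of this kind of code was made by
expert inspection, and these defaults encode that judgement
conservatively rather than derive from any fitted model.

# Numerical and design choices, collected

* Coordinates are 0-based half-open internally, converted to 1-based
  inclusive only at the GFF3 boundary; strand is handled by
  reverse-complementing before translation.
* All alignments use BLOSUM62 with gap open 11 / extend 1; local for
  search, global for the query-to-panel mapping.
* Determinism: a single seed drives every stochastic step; ties anywhere
  (consensus votes, majority bases) break lexicographically; reruns are
  byte-identical, which the suite asserts on output files.
* Problem sizes used by the test suite: unit tests run a 6–8-gene,
  12-taxon configuration (~3.5 kb of coding sequence); the study-scale
  property checks use the full default configuration — 13 genes, 30 taxa,
  ~20 kb circular genome at 40× — with 50 replicates for code recovery
  and its negative control, 20 for assembly and frameshift repair, and 6
  for the fragment rule. These sizes give the binomial assertions
  meaningful resolution while keeping a full run in the minutes range.
* `run_pipeline()` writes blob table, assembly, GFF3, presence/absence
  matrix, stop-site and tally TSVs, code-call and inferred-code JSON, and
  a report with per-stage parameters, seed, and input digests.

# Known limitations

* The generator evolves proteins without indels, so panels are trivially
  aligned and the gap/occupancy exclusion paths, while implemented and
  unit-tested on constructed columns, are not stressed by realistic
  alignment error; likewise rRNA genes, tRNAs (absent from these genomes)
  and intragenomic polymorphism are not modelled.
* Planting recoded codons only at conserved sites makes every planted
  site detectable; real genomes put many in-frame TAAs in divergent
  regions where the tally must discard them. Results on synthetic data
  bound what the method can do under favourable signal, not under
  adversarial divergence.
* The nucleotide-level seeding mode of the original contig search (50%
  mismatch, word length 5) is exposed as configuration but protein-space
  seeding is the supported default — at these divergences nucleotide
  identity carries little signal.
* Bait-and-extend assumes substitution-only errors (no gaps), matching
  its recruitment rule; indel-rich reads would stall extension.
* The pairwise stop profile reports counts for one protein pair at a
  time; aggregation across pairs is left to the caller.
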