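---
title: "Comparative dRNA-seq analysis of orthologous transcription start sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative dRNA-seq analysis of orthologous transcription start sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthotss)
```

## The analysis

`orthotss` implements a comparative primary-transcriptome analysis for a pair
of related bacterial genomes profiled by differential RNA-seq (dRNA-seq)
under two phenotypic conditions. dRNA-seq sequences each RNA sample twice:
once after treatment with a terminator-5′-phosphate-dependent exonuclease
(TEX), which degrades processed transcripts carrying a 5′ monophosphate and
thereby enriches primary transcripts with an intact 5′ triphosphate, and once
untreated. A transcription start site (TSS) announces itself as a sharp rise
of 5′-end read coverage that is stronger in the TEX-treated library than in
the untreated one.

The pipeline proceeds in six stages, each an exported function group:

1. **Coverage** (`clip_read`, `filter_alignments`,
   `coverage_from_alignments`). Reads are clipped of ligation-artifact
   homopolymers: a trailing A-run (or leading T-run) longer than the longest
   run of that base observed in the genome is removed entirely, on the
   reasoning that none of an artifact run is genomic signal. Reads shorter
   than 20 nt after clipping are dropped. An alignment is kept when it spans
   at least 80% of the read, has at most 4 mismatches, no gaps and an
   e-value of at most 10⁻⁴; reads overlapping rRNA operons or with more than
   one best-scoring alignment are discarded entirely. Per-position 5′-end
   counts (alignment start on the plus strand, end on the minus strand) are
   scaled by `min(library sizes) / library size`, so every library totals the
   smallest library's depth.

2. **TSS calling** (`call_tss`, `cluster_tss`, `unify_conditions`). A
   position is a TSS candidate when TEX(+) coverage rises by at least
   `min_step` (default 5 normalized units) over the immediately upstream
   position and the pseudocounted ratio `(TEX(+)+1)/(TEX(−)+1)` is at least
   `min_enrich` (default 2). This step-plus-enrichment rule is a deliberately
   minimal, fully documented stand-in for dedicated TSS prediction tools,
   whose internal parameters are not part of this design; both thresholds are
   configurable. Candidates are chain-link clustered at 30 bp within a
   condition and the per-condition sets are unified with a 35 bp window,
   keeping the highest-step representative (chain linkage over sorted
   positions is equivalent to a sliding window here). Each unified TSS
   carries a per-condition transcription level, defined as the normalized
   TEX(+) 5′-end coverage at the representative position — step height and
   level are both retained, and the level is what enters fold changes.

3. **Classification** (`classify_tss`, `derive_utr_threshold`,
   `scan_pribnow`). A TSS is genic (g) when a same-strand ORF starts within
   1000 nt downstream (strictly positive distance, strand-aware), internal
   (i) when inside a same-strand ORF, antisense (a) when inside an
   opposite-strand ORF, and intergenic (n) otherwise; all applicable labels
   are kept (e.g. `gi`). The 1000 nt default is the operational rule; the
   species-specific alternative — the mean intergenic distance — is provided
   as `derive_utr_threshold`. A genic TSS is associated with the nearest
   qualifying downstream ORF only, which keeps one 5′ UTR per TSS and makes
   the UTR-alignment relocation below unambiguous. A simple consensus scan
   for the −10 (Pribnow) box hexamer `TA-N₃-[T/A]` is included; it reports
   hexamer offsets walking upstream from the TSS (position 1 = the
   immediately upstream nucleotide).

4. **Orthology** (`build_single_copy_orthologs`, `global_align`,
   `codon_alignment_map`). Cross-species protein similarity is searched
   all-against-all with Needleman–Wunsch global alignment (BLOSUM62, gap
   open 10, gap extend 0.5 — classical `needle` defaults). Because a global
   score has no e-value, the hit threshold is calibrated on a null of 300
   residue-shuffled cross-species pairs: no shuffled pair may pass
   (`calibrate_score_threshold`). Reciprocal best hits with a unique maximum
   on both sides form candidate pairs; tied best scores mark a family as not
   single-copy and exclude its genes. Pairs below 30% global protein
   identity are dropped. Externally computed tabular protein hits can be
   supplied instead of the internal search, filtered at 30% local identity
   and e-value 10⁻¹⁰. Each retained pair carries three alignments: protein,
   codon (each protein column expanded to three nucleotide columns through
   the CDS; the stop codon is outside the map) and the two 1000 nt 5′-UTR
   regions aligned as nucleotides (match 5, mismatch −4).

5. **Positional TSS orthology** (`ortho_tss_pairs`,
   `match_orthologous_tss`, `locus_identity`). TSSs of the two genes of an
   ortholog pair are relocated into the shared alignment — genic TSSs into
   the UTR alignment, internal TSSs into the codon alignment, antisense TSSs
   through the sense ORF's codon coordinates (the position of the
   complementary nucleotide), which keeps a single alignment per pair. Two
   TSSs at most 35 alignment columns apart are positional orthologs; the
   rest are singletons. Column distance counts gap columns: that is the only
   definition invariant to which row carries the gaps. Matching is greedy by
   ascending column distance with ties broken towards the smaller species-a
   column; the mirror-symmetry of the result is property-tested. A TSS with
   several class labels participates in each class's matching independently,
   mirroring per-class conservation accounting. For every matched pair the
   ±35 nt locus windows (71 nt, truncated at replicon edges) are aligned and
   their percent identity recorded.

6. **Fold-change screening and statistics** (`fold_change`,
   `select_consistent_candidates`, `class_count_table`,
   `fisher_conservation_fdr`, `trend_test_linear`, `wilcoxon_paired`). The
   per-TSS condition fold change is `log2(level_branchless /
   level_true_branching)`, defined only when both levels are positive — no
   pseudocount is added, a zero level excludes the TSS. Among orthologous
   TSS pairs with both fold changes defined, the `ceil(0.05 · n)` pairs with
   the largest `|fc_a + fc_b|` among same-sign (quadrant I/III) pairs are
   flagged as consistent extreme candidates; the ranking statistic is
   configurable (`sum`, `min`, `product`), the 5% tail applies to the global
   pair count rather than per class, and inconsistent pairs are never
   candidates. The conservation summary reproduces the per-class count
   table, compares classes pairwise with two-sided Fisher's exact tests
   under Benjamini–Hochberg correction (multi-class TSSs excluded from the
   contingency analysis), tests for a linear trend of conservation across
   protein-identity bins (Cochran–Armitage via `prop.trend.test`; seven
   10-point bins spanning 30–100% by default, a choice made here since no
   binning is prescribed), and compares locus identity with protein identity
   by a paired Wilcoxon signed-rank test.

## The synthetic study

`generate_truth()` and `simulate_libraries()` build a fully specified
two-species study so every stage is testable without external data. The
default configuration (`sim_config()`) is the study design the analysis
assumes: 200 single-copy orthologous ORFs (120–280 codons) separated by
250–500 nt spacers on a single linear replicon, an AT-rich base composition,
and a second species derived by per-site substitution at 5% divergence with
no indels — so homologous coordinates coincide and the planted orthologous
TSS positions are exactly well defined. Start and stop codons are protected
and codons mutated into stops revert, keeping every ORF translatable.

Per gene, a genic, internal and antisense TSS locus is planted with
probabilities 0.9, 0.5 and 0.45; each locus is orthologous with probability
0.7 (optionally class-specific), otherwise lineage-specific, and 20 extra
lineage-specific sites plus 10 intergenic tail sites are planted per
species. Planted base heights are uniform on 100–400 normalized units.
Orthologous non-extreme loci share a common log2 fold-change component
(sd 0.4) plus species noise (sd 0.2), which produces the positive
cross-species fold-change correlation the screening stage expects; 3% of
orthologous loci instead receive a consistent extreme fold change (same
sign, magnitude 4–5 per species, drawn from the upper half of the height
range so the weak condition stays well above the detection floor).

Libraries follow the TEX-by-condition design: four per species. TEX(+)
counts at a planted TSS are Poisson at the planted level; TEX(−) counts are
the level divided by the TEX enrichment ratio (default 10); background 5′
ends arrive as per-position Poisson noise (rate 0.1 per position and
strand, which also gives the TEX(−) libraries the processed-end background
that makes depth normalization meaningful); read 5′ ends receive truncated
Gaussian jitter (sd 1 nt, bounded at ±3). With these defaults a TEX(+)
library holds roughly 10⁵ 5′ ends over the ≈190 kb replicon. Exact library
totals can be requested (`library_sizes`), in which case reads are drawn
multinomially. Each library also emits per-read alignment records including
a small admixture of short-span and multi-mapping decoys so the alignment
filters are exercised end to end.

What the simulation does **not** emulate: replicate variance (the emulated
design pools biological replicates before sequencing, so one library per
TEX-by-condition cell is the faithful choice and no replicate-aware
confidence is modelled); rRNA operons; genomic rearrangements or indels
between the species; sequence-level read errors (alignments are emitted
directly); and promoter sequence determinants (planted TSSs are positional,
not motif-driven). Passing recovery tests therefore demonstrate the
correctness of the pipeline's logic under its stated assumptions, not
performance on real libraries, where indels shift alignment columns and
replicate noise widens fold-change estimates.

## Numerical choices and edge cases

* **Pseudocounts.** TSS calling uses `(TEX(+)+1)/(TEX(−)+1)` to avoid
  division by zero; fold changes use none — zero levels exclude a TSS, as
  the screening rule demands.
* **Replicon edges.** The first position of a plus-strand vector (last on
  minus) has no upstream neighbour and is never callable; locus and UTR
  windows truncate at replicon edges rather than erroring.
* **Normalization degeneracy.** In a background-free limit the TEX(−)
  library shrinks towards zero and smallest-library scaling would exactly
  cancel the TEX enrichment signal; real (and default synthetic) TEX(−)
  libraries carry processed-end background, which keeps library sizes
  comparable. The noise-free recovery test therefore supplies an explicit
  zero TEX(−) track.
* **Ties.** Clustering resolves equal step heights towards the smaller
  coordinate; candidate ranking resolves equal scores towards the smaller
  species-a TSS id; tied best hits in the ortholog search exclude the family
  (not single-copy).
* **Quadrants.** Fold-change quadrants follow the standard Cartesian
  convention with species a on the x-axis: I both positive, III both
  negative; II and IV are inconsistent and never candidates.
* **Exact tests.** Fisher p-values come from `stats::fisher.test` and are
  property-tested against full hypergeometric enumeration for all 2×2
  tables with n ≤ 30; tables with a zero margin return p = 1 by convention.
  The Wilcoxon signed-rank test enumerates all sign assignments (with
  midranks under ties) for up to 14 informative pairs — `stats::wilcox.test`
  cannot be exact under ties — and delegates to `wilcox.test` above that.
* **Problem sizes.** The recovery tests run the default 200-gene scenario
  (~10⁵ 5′ ends per TEX(+) library), which completes in about a minute; the
  statistical power of the class contrast is checked with 200 replicate
  draws at the planted class-specific conservation rates at a 60-gene
  scale.

## Known limitations

The per-species caller is a stand-in: it uses one global step and enrichment
threshold rather than locally adaptive criteria, so very weak TSSs near the
background are governed entirely by `min_step`. Antisense TSS relocation
through the sense ORF's codon alignment assumes the antisense TSS falls
within the annotated ORF (by classification it does). The trend test
defaults to identity deciles over 30–100% and needs at least two non-empty
bins, which low-divergence synthetic data may not provide — the study runner
reports `NULL` in that case rather than failing. The three-way extension to
a second comparison species is structurally supported (every stage is a pure
function of one genome pair) but not separately validated.
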