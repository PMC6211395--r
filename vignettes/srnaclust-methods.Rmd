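---
title: "Methods: small RNA cluster annotation with srnaclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA cluster annotation with srnaclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnaclust)
```

## The annotation model

`srnaclust` annotates small RNA producing loci from mapped reads alone,
exploiting two population-level properties rather than per-read features:

1. **Read diversity.** miRNA biogenesis is positionally precise, so a miRNA
   locus emits few distinct reads at high abundance. Dicer processing of
   long double-stranded RNA (endo-siRNAs) and piRNA biogenesis emit many
   distinct, individually rare reads. The *uniformity index* of a cluster,
   `UI = total count / distinct reads`, captures this: UI ≥ 1, with
   equality exactly when every distinct read is a singleton. Two reference
   cases anchor the scale: 16 counts over 3 distinct reads give
   UI = 5.3; 16 counts over 12 distinct reads give UI = 1.3.
2. **Read length.** Dicer products peak at 20–22 nt; piRNAs at 26–28 nt in
   most non-bilaterian lineages, 24–26 nt in *Drosophila*; the ctenophore
   25-mer class at 24–26 nt.

The pipeline stages and their contracts:

* **Multimapper filtering.** Mapping multiplicity is carried per sequence
  (`n_mappings`), never inferred from duplicate rows, so the 1–50 rule is
  exact even on subset files. Reads mapping ≥ 51 times are removed;
  analyses run in parallel on all retained reads and on the uniquely
  mapping subset. A multi-mapping sequence contributes its count once to
  library depth, but each retained mapping can join a cluster.
* **rRNA exclusion** removes any read overlapping an annotated rRNA by
  ≥ 1 nt. The overlap is strand-agnostic by default (the most permissive
  removal is the conservative choice for downstream classes; sense-only
  removal is available via `stranded = TRUE`).
* **Clustering.** Reads merge transitively when interval gaps are
  ≤ 150 bp — roughly the span of a long pre-miRNA, so products of one
  primary transcript fall together. A cluster must hold ≥ 3 distinct
  `(start, end, strand, sequence)` tuples that are not all perfectly
  overlapping, and span ≥ 51 bp. The span is the merged interval length
  (not summed coverage); both interpretations were defensible and the span
  reading is the configurable default. Reads are canonically sorted before
  merging, so cluster calls are order-independent.
* **Classification.** Clusters overlapping known miRNA / tRNA / snoRNA
  annotation (≥ 1 nt) are labelled first, with precedence
  known_miRNA > tRNA > snoRNA. The rest go through the peak-dominance
  rule: with modal read length `L` (ties break to the shorter length), a
  class whose peak set contains `L` is assigned only when the summed count
  over `L − 1 .. L + 1` strictly exceeds the summed count of all other
  lengths. Equality leaves the cluster unclassified — the rule says
  "greater than", and we read it strictly. The halo uses `L ± 1` even when
  a flank lies outside the class's peak set. High-uniformity clusters with
  Dicer-length peaks are routed to `miRNA_candidate_HU` instead of
  `endo_siRNA`: in practice such clusters are unannotated miRNAs,
  tRNA/snoRNA fragments or hairpin RNAs, and silently calling them
  endo-siRNAs would contaminate that class.
* **Signatures.** Bias matrices anchor reads at the 5′ end and report, per
  position, each base's percentage among reads long enough to reach it
  (count-weighted by default; per-distinct-read mode available, since
  either weighting is defensible). Detection thresholds are explicit
  numeric surrogates for what is usually judged by eye from bias plots:
  ping-pong requires U modal at position 1 (≥ 40 %) *and* A modal at
  position 10 (≥ 35 %); the downstream-G call requires the mean G% beyond
  position 25 to exceed 1.25× the mean over positions 2–25. Defaults were
  fixed once against the simulated null (false-positive rate ≤ 5 % at
  n = 1000 reads) and the planted signals, and are configurable.
* **Structure.** Cluster spans are folded strand-resolved: single-strand
  clusters on their read strand; mixed clusters on both strands keeping
  the lower minimum free energy, ties going deterministically to plus. The
  folding engine is a contract. The default built-in engine is a weighted
  Nussinov base-pair maximisation (Rcpp) with an energy proxy of −1 per
  GC, −0.7 per AU and −0.5 per GU pair, a minimum hairpin loop of 3 nt and
  a maximum pairing span (default 150 nt, matching the cluster window);
  ViennaRNA's `RNALfold` can be swapped in (`backend = "vienna"`) for full
  nearest-neighbour thermodynamics. Significance comes from
  Altschul–Erickson dinucleotide-preserving shuffles — dinucleotide rather
  than mononucleotide shuffling is the standard null for RNA folding since
  it preserves stacking statistics — with the add-one empirical p-value
  `p = (1 + #{MFE_shuffle ≤ MFE_native}) / (N + 1)`, bounded away from
  zero in `[1/(N+1), 1]`. Native and shuffled sequences always use the
  same engine, so engine bias cancels in the comparison.
* **Genomic context.** Exons, introns and UTRs overlapping a predicted
  transposon (≥ 1 nt) are masked out first. A cluster is attributed to
  every element class covering ≥ 51 % of its span (computed against the
  class's interval union — the union reading of the rule; single-interval
  mode would be stricter and is not what coverage-style totals suggest);
  clusters reaching no class are intergenic. Multi-attribution is
  deliberate: genomic element classes overlap, so per-class totals may
  slightly exceed 100 %. Single-label summaries use the precedence
  exon > utr5 > utr3 > intron > transposon_known > transposon_unknown.
* **Overlap enrichment** against a reference locus set uses a
  length-preserving permutation null: cluster intervals are re-placed
  uniformly within their own scaffolds and the count of reference-hitting
  clusters is recomputed per permutation, again with the add-one p-value.
  This construction is the package's own; it conditions on scaffold
  assignment and cluster lengths, which is the minimal exchangeable null
  for interval overlap.
* **cis-NAT prediction** follows the ≥ 1 nt antisense-overlap definition;
  the relation is symmetric and both partners are reported.
* **Co-expression links** join per-stage clusters into loci by ≥ 1 nt span
  overlap (per-stage calling with overlap identity, rather than joint
  calling, so stages remain independently reproducible; joint mode can be
  emulated by pooling libraries). One link per unordered stage pair per
  locus, class-matched by default, requiring ≥ 1 read in both stages.

## Key parameters

| parameter | default | unit | why |
|---|---|---|---|
| `window` | 150 | bp | pre-miRNA-scale merge gap; also the fold span |
| `min_distinct` | 3 | reads | minimum evidence for a locus |
| `min_cluster_len` | 51 | bp | shortest credible precursor span |
| `max_mappings` | 50 | loci | repeat-noise cut-off (1–50 rule) |
| `hu_threshold` | 3 | UI | separates the 5.3 / 1.3 reference cases with margin; quantile mode available for depth robustness |
| `n_shuffles` | 100 | — | p-value floor 1/101 < 0.01 |
| `min_fraction` | 0.51 | — | majority-of-cluster context rule |
| `u1_min`, `a10_min` | 40, 35 | % | ping-pong thresholds (see above) |
| `dg_factor` | 1.25 | fold | downstream-G enrichment factor |

The HU threshold deserves a note: no numeric value is canonical, only the
requirement that miRNA-like and siRNA-like uniformity separate. The default
3 puts the reference cases (5.3, 1.3) on opposite sides with comfortable
margin; per-library quantile thresholding (`segregate_hu_lu(quantile=)`)
is provided because raw UI scales with depth.

## What the synthetic data emulates — and what it does not

`simulate_genome()` plants, on i.i.d.-uniform random scaffolds
(3 × 60 kb by default): 8 miRNA hairpin cassettes (30 nt arms, dominant
mature read ≈ 100 counts plus shifted variants and a star read); 12
endo-siRNA inverted repeats (170 bp, 30 distinct 20–22 nt reads, counts
≈ 1.3); 12 piRNA loci (40 distinct 26–28 nt reads; half reside in
transposon families pasted at 3 copies, making their reads exact
3-site multimappers) with 5′ U frequency 0.8, position-10 A frequency 0.6
and a downstream-G tail bias of 0.5; 6 25-mer loci (24–26 nt, 5′ U only);
2 rRNA loci; and gene models with exon/intron/UTR structure, half of the
endo loci sitting inside overlapping antisense (cis-NAT) gene pairs.
Sequence biases are written into the genome at pre-drawn template
positions, so every simulated read matches the genome exactly and
`n_mappings` is computed by exhaustive occurrence search, not assumed.

Deliberately not emulated: sequencing error and adapter artefacts,
realistic transposon family divergence, non-uniform genomic base
composition, expression noise between biological replicates, and
partially-overlapping repeat families. Consequently, passing the planted
recovery tests demonstrates the correctness of the rules and their
composition — not robustness to mapping ambiguity from diverged repeats or
to contaminating RNA classes, which real libraries contain. One visible
artefact of the construction: reads from hairpin stems also match the
antisense arm of their own locus, so simulated hairpin clusters count as
multi-mapping; this is why the worked example reports endo-siRNA clusters
in the multi-mapping column.

## Numerical choices and degenerate inputs

* UI is stored at full precision; reports round to 2 decimals (the two
  reference cases are quoted at 1 decimal).
* Modal-length ties break to the shorter length; fold-strand ties to plus;
  the Mnemiopsis 26-nt peak, eligible for both piRNA and 25-mer, goes to
  whichever full peak set carries more summed count, ties to piRNA (the
  choice is flagged in the classifier documentation as a convention).
* Empty inputs propagate as empty results; zero distinct reads, zero
  depth, empty histograms and non-ACGU folding input raise errors rather
  than returning sentinels.
* Homopolymers shuffle to themselves, so their shuffle-test p-value is 1
  by construction — the add-one formula never returns 0 or an undefined
  value.
* Positions not covered by any read are reported as missing, not 0 %, in
  bias matrices; downstream-G returns an explicit `indeterminate` status
  when no read extends past the boundary position.

## Problem sizes used by the test suite

The shipped tests run the full pipeline on the default three-scaffold
synthetic genome (~50 planted loci, ~1 800 mapping records), check the
classifier against an independent oracle on 10 000 random histograms per
preset, calibrate the ping-pong call on 200 uniform-null libraries of
1 000 reads, the shuffle test on 200 i.i.d. 70-mers at 100 shuffles each
(Kolmogorov–Smirnov against uniform), and the enrichment permutation test
on 100 null replicates of 1 000 permutations. These sizes give stable
statistics while keeping a full run in minutes on one core.

## Known limitations

* The built-in folding engine maximises weighted base pairs; it is a
  proxy, not nearest-neighbour thermodynamics. Comparative uses (native
  vs shuffle, class vs background) are robust to this; absolute MFE values
  are not meaningful in kcal/mol terms unless the ViennaRNA backend is
  used.
* De novo miRNA hairpin validation is out of scope: high-uniformity
  Dicer-length clusters are only *routed* to candidate review.
* The read input format assumes collapsed reads with externally computed
  mapping multiplicity; the package does not realign.
* Species-scale biological conclusions require real libraries and genome
  assemblies; everything the tests assert is about the method's internal
  correctness and calibration.
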