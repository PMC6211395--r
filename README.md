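# srnaclust

Annotation of the RNA-interference repertoire of a genome — miRNA-like,
endo-siRNA, piRNA and ctenophore-style 25-mer loci — from mapped small RNA
sequencing libraries.

Small RNA classes differ less in what their reads look like individually
than in how read populations are organised over their source loci. miRNA
biogenesis is precise, so a miRNA locus yields a few distinct reads of high
abundance; Dicer processing of long double-stranded precursors (endo-siRNAs)
and the piRNA pathway both produce many distinct reads that are individually
rare. `srnaclust` turns that contrast into an annotation pipeline for any
genome with mapped small RNA data, without requiring curated miRNA/piRNA
databases.

## The statistic at the core

Reads are merged into clusters (single-linkage, gap ≤ 150 bp), and each
cluster is scored with the **uniformity index**

    UI = total read count of the cluster / number of distinct reads

UI ≥ 1 always; UI = 1 means every distinct read is a singleton. A miRNA-like
cluster of 16 counts over 3 distinct reads scores 16/3 = 5.3, while an
endo-siRNA-like cluster of 16 counts over 12 distinct reads scores
16/12 = 1.3. Thresholding UI (default 3, or a per-library quantile)
separates high-uniformity (HU) clusters — miRNAs, plus tRNA/snoRNA/hairpin
RNA loci for secondary review — from low-uniformity endo-siRNA and piRNA
clusters. Because raw UI grows with sequencing depth, `normalize_ui()`
divides by library depth for between-library comparisons.

Around the index the package implements:

* the 1–50 multimapper rule (`filter_multimappers`; reads mapping ≥ 51
  times are discarded, a uniquely mapping subset is carried in parallel)
  and rRNA exclusion;
* cluster calling with the ≥ 3 distinct (non-perfectly-overlapping) reads
  and ≥ 51 bp rules (`build_clusters`);
* read-length–peak classification (`classify_clusters`): a cluster is
  endo-siRNA / piRNA / 25-mer when the counts at its modal read length ± 1 nt
  strictly outweigh all other size classes, with presets
  `nonbilaterian` (piRNA 26–28 nt), `drosophila` (24–26 nt) and
  `mnemiopsis` (adds 24–26 nt 25-mers);
* biogenesis signatures from 5′-anchored positional base-bias matrices:
  ping-pong (1U/10A), 5′ U bias, downstream-G enrichment past position 25
  (`positional_bias`, `detect_ping_pong`, `detect_downstream_g`);
* precursor structure testing: strand-resolved minimum-free-energy folding
  (built-in base-pair–maximisation engine in C++, or ViennaRNA's `RNALfold`
  as a drop-in backend) compared against Altschul–Erickson
  dinucleotide-preserving shuffles, `p = (1 + #{MFE_shuffle ≤ MFE_native})
  / (N + 1)` (`randfold_test`, `fold_clusters`);
* genomic context: ≥ 51 % overlap attribution to
  exon/intron/UTR/transposon/intergenic after transposon-precedence masking,
  genome coverage, and a permutation test of overlap enrichment against
  reference locus sets (`assign_context`, `overlap_enrichment_test`);
* cis-NAT prediction (genes overlapping an opposite-strand gene by ≥ 1 nt)
  and the fraction of gene-aligned unique endo-siRNA clusters arising from
  cis-NAT pairs (`predict_cis_nats`, `cis_nat_srna_fraction`);
* co-expression link tables across developmental libraries
  (`coexpression_links`), Circos-ready;
* a fully seeded synthetic-data generator planting all locus classes with
  known ground truth (`sim_spec`, `simulate_genome`, `simulate_library`),
  so the whole pipeline is testable without downloads.

## Worked example

```r
library(srnaclust)

sim  <- simulate_genome(sim_spec(), rng_seed = 1)   # toy genome + truth
lib  <- simulate_library(sim, rng_seed = 2)          # mapped reads
filt <- filter_multimappers(lib)                     # the 1-50 rule
reads <- exclude_rrna(filt$all_reads, sim$tracks$rRNA)

cl <- build_clusters(reads)                          # 150-bp window
cl <- classify_clusters(cl, sim$tracks, class_config("mnemiopsis"))
tabulate_classes(list(sim = cl))
```

```
  library miRNA miRNA_candidate_HU unique_endo_siRNA multi_endo_siRNA
1     sim     8                  0                 0               12
  unique_piRNA multi_piRNA unique_mer25 multi_mer25 unclassified
1            6          18            6           0            0
```

All 8 planted miRNA hairpins are annotated via the known-miRNA track, the
12 endo-siRNA inverted repeats and 6 25-mer loci get their length-peak
labels, and the 24 piRNA cluster calls split into 6 unique loci and 18
transposon-family copies (multimappers). Against the generator's ground
truth:

```r
evaluate_recovery(cl, sim$truth)
```

```
    class n_loci n_recovered recall
1   mirna      8           8      1
2    endo     12          12      1
3   pirna     24          24      1
4   mer25      6           6      1
5 overall     50          50      1
```

The uniformity contrast that drives the method is visible directly: mean UI
is 35.4 for the miRNA clusters versus 1.4 for the endo-siRNA clusters in
this run.

A command-line driver with composable subcommands (`simulate`, `cluster`,
`classify`, `signatures`, `structure`, `context`, `links`, `run`) is
installed at `system.file("cli", "srna-classify.R", package = "srnaclust")`.

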