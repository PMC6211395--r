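Package: srnaclust
Title: Clustering and Annotation of Small RNA Loci from Mapped Read Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Annotates the small RNA repertoire of a genome from mapped small
    RNA sequencing libraries. Mapped reads are merged into genomic clusters,
    each cluster is scored with a uniformity index (total read abundance over
    the number of distinct reads) that separates miRNA-like high-uniformity
    loci from low-uniformity endo-siRNA and piRNA loci, and clusters are
    classified by the read-length composition of their constituent small RNAs.
    Additional tools profile biogenesis signatures (ping-pong 1U/10A bias,
    5' uridine bias, downstream guanosine enrichment), test putative precursor
    secondary structure against dinucleotide-shuffled nulls, attribute clusters
    to genomic elements (exon, intron, UTR, transposon, intergenic), predict
    cis-natural antisense transcript gene pairs, and tabulate cluster
    co-expression across developmental stages. A seeded synthetic-data module
    generates toy genomes and libraries with planted loci of every class so the
    whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr,
    Rsamtools
Config/testthat/edition: 3
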