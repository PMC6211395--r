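#' Remove genic intervals that overlap transposons
#'
#' Exons, introns and UTRs overlapping a predicted transposon by at least one
#' nucleotide are removed from their tracks, so transposon-resident copies of
#' genic elements do not dilute the genic context classes.
#'
#' @param tracks Named list of annotation `GRanges` (keys from the element
#'   classes; transposon tracks are `transposon_known` /
#'   `transposon_unknown`).
#' @return The list with masked genic tracks.
#' @export
mask_genic_by_transposon <- function(tracks) {
  tp <- c(tracks[["transposon_known"]], tracks[["transposon_unknown"]])
  if (is.null(tp) || length(tp) == 0) return(tracks)
  for (cls in c("exon", "intron", "utr5", "utr3")) {
    trk <- tracks[[cls]]
    if (is.null(trk) || length(trk) == 0) next
    hit <- GenomicRanges::countOverlaps(trk, tp, ignore.strand = TRUE) > 0
    tracks[[cls]] <- trk[!hit]
  }
  tracks
}

CONTEXT_CLASSES <- c("exon", "utr5", "utr3", "intron",
                     "transposon_known", "transposon_unknown")

#' Attribute clusters to genomic element classes
#'
#' For every cluster and element class, the fraction of the cluster span
#' covered by the union of that class's intervals is computed
#' (strand-agnostic). Every class reaching `min_fraction` is recorded -- a
#' cluster sitting in a region encoding multiple element types is assigned to
#' all of them, which is why per-class totals can exceed 100%. A cluster
#' reaching no class is `intergenic`. The single `context` label used in
#' summaries follows the precedence
#' exon > utr5 > utr3 > intron > transposon_known > transposon_unknown.
#'
#' @param clusters Clusters (`GRanges`).
#' @param tracks Named list of annotation tracks, already transposon-masked
#'   (see [mask_genic_by_transposon()]).
#' @param min_fraction Minimum overlapped fraction of the cluster length
#'   (default 0.51, i.e. at least 51%).
#' @return A `data.frame` with one row per cluster: `cluster_id`, `context`
#'   (primary label), `contexts` (comma-separated qualifying classes) and
#'   `max_fraction`; the per-class fraction matrix is attached as attribute
#'   `fractions`.
#' @export
assign_context <- function(clusters, tracks, min_fraction = 0.51) {
  n <- length(clusters)
  frac <- matrix(0, nrow = n, ncol = length(CONTEXT_CLASSES),
                 dimnames = list(NULL, CONTEXT_CLASSES))
  for (cls in CONTEXT_CLASSES) {
    trk <- tracks[[cls]]
    if (is.null(trk) || length(trk) == 0) next
    u <- GenomicRanges::reduce(GenomicRanges::granges(trk),
                               ignore.strand = TRUE)
    ov <- GenomicRanges::findOverlaps(clusters, u, ignore.strand = TRUE)
    if (length(ov) == 0) next
    inter_w <- GenomicRanges::width(IRanges::pintersect(
      IRanges::ranges(clusters)[S4Vectors::queryHits(ov)],
      IRanges::ranges(u)[S4Vectors::subjectHits(ov)]))
    bp <- tapply(inter_w, S4Vectors::queryHits(ov), sum)
    idx <- as.integer(names(bp))
    frac[idx, cls] <- as.numeric(bp) / GenomicRanges::width(clusters)[idx]
  }
  qualifies <- frac >= min_fraction
  primary <- apply(qualifies, 1, function(q) {
    hit <- CONTEXT_CLASSES[q]
    if (length(hit) == 0) "intergenic" else hit[1]
  })
  contexts <- apply(qualifies, 1, function(q) {
    hit <- CONTEXT_CLASSES[q]
    if (length(hit) == 0) "intergenic" else paste(hit, collapse = ",")
  })
  ids <- S4Vectors::mcols(clusters)$cluster_id
  if (is.null(ids)) ids <- sprintf("cl%05d", seq_len(n))
  out <- data.frame(cluster_id = ids, context = primary, contexts = contexts,
                    max_fraction = apply(frac, 1, function(x) {
                      if (length(x) == 0) 0 else max(x)
                    }),
                    stringsAsFactors = FALSE)
  attr(out, "fractions") <- frac
  out
}

#' Genome coverage of annotation tracks
#'
#' Percentage of the genome covered by the interval union of each element
#' class.
#'
#' @param tracks Named list of annotation `GRanges`.
#' @param genome_lengths Named numeric vector of scaffold lengths (e.g.
#'   `setNames(Biostrings::width(genome), names(genome))`).
#' @return `data.frame` with `element_class`, `bp` and `percent`.
#' @export
genome_coverage <- function(tracks, genome_lengths) {
  total <- sum(as.numeric(genome_lengths))
  rows <- lapply(names(tracks), function(cls) {
    trk <- tracks[[cls]]
    bp <- 0
    if (!is.null(trk) && length(trk) > 0) {
      sc <- as.character(GenomicRanges::seqnames(trk))
      unknown <- setdiff(unique(sc), names(genome_lengths))
      if (length(unknown) > 0) {
        stop_srna("track '%s' references unknown scaffold '%s'",
                  cls, unknown[1])
      }
      if (any(GenomicRanges::end(trk) > genome_lengths[sc])) {
        stop_srna("track '%s' has an interval beyond its scaffold end", cls)
      }
      u <- GenomicRanges::reduce(GenomicRanges::granges(trk),
                                 ignore.strand = TRUE)
      bp <- sum(as.numeric(GenomicRanges::width(u)))
    }
    data.frame(element_class = cls, bp = bp, percent = 100 * bp / total,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-class genomic context summary
#'
#' The stacked-percentage view: for each cluster class, the percentage of its
#' clusters attributed to each genomic element class. Because one cluster may
#' qualify for several elements, class totals may slightly exceed 100%.
#'
#' @param clusters Classified clusters.
#' @param assignment Output of [assign_context()] for the same clusters.
#' @return `data.frame` with `class`, `element_class`, `percent`, `n`.
#' @export
context_summary <- function(clusters, assignment) {
  frac <- attr(assignment, "fractions")
  lab <- as.character(S4Vectors::mcols(clusters)$class)
  elements <- c(CONTEXT_CLASSES, "intergenic")
  rows <- lapply(unique(lab), function(cls) {
    sel <- lab == cls
    n <- sum(sel)
    qual <- strsplit(assignment$contexts[sel], ",", fixed = TRUE)
    data.frame(
      class = cls,
      element_class = elements,
      percent = vapply(elements, function(e) {
        100 * mean(vapply(qual, function(q) e %in% q, logical(1)))
      }, numeric(1)),
      n = n, stringsAsFactors = FALSE, row.names = NULL
    )
  })
  do.call(rbind, rows)
}

#' Permutation test of cluster/reference overlap enrichment
#'
#' Observed statistic: the number of clusters overlapping at least one
#' reference locus by at least one nucleotide. The null distribution is
#' built by placing intervals of the same lengths uniformly at random within
#' their own scaffolds, `n_permutations` times; the p-value uses the add-one
#' convention `p = (1 + #\{null >= observed\}) / (n_permutations + 1)`.
#'
#' @param clusters Clusters (`GRanges`).
#' @param reference_loci Reference locus set (`GRanges`).
#' @param genome_lengths Named scaffold length vector.
#' @param n_permutations Number of random placements (default 1000).
#' @param rng_seed Optional seed.
#' @return List with `observed`, `expected` (null mean), `p` and
#'   `n_permutations`.
#' @export
overlap_enrichment_test <- function(clusters, reference_loci, genome_lengths,
                                    n_permutations = 1000L, rng_seed = NULL) {
  if (n_permutations < 100) stop_srna("n_permutations must be >= 100")
  sc <- as.character(GenomicRanges::seqnames(clusters))
  w <- GenomicRanges::width(clusters)
  fit <- w <= genome_lengths[sc]
  if (any(!fit)) {
    warning(sprintf("%d cluster(s) longer than their scaffold were skipped",
                    sum(!fit)))
    clusters <- clusters[fit]
    sc <- sc[fit]
    w <- w[fit]
  }
  observed <- sum(GenomicRanges::countOverlaps(clusters, reference_loci,
                                               ignore.strand = TRUE) > 0)
  if (length(reference_loci) == 0 || length(clusters) == 0) {
    return(list(observed = observed, expected = 0, p = 1,
                n_permutations = as.integer(n_permutations)))
  }
  # per-scaffold disjoint reference unions for fast membership tests
  ref <- GenomicRanges::reduce(GenomicRanges::granges(reference_loci),
                               ignore.strand = TRUE)
  ref_by <- split(IRanges::ranges(ref),
                  as.character(GenomicRanges::seqnames(ref)))
  starts <- lapply(ref_by, IRanges::start)
  ends <- lapply(ref_by, IRanges::end)
  cl_by <- split(seq_along(clusters), sc)
  max_start <- genome_lengths[sc] - w + 1

  null_counts <- with_rng(rng_seed, {
    vapply(seq_len(n_permutations), function(rep) {
      hits <- 0L
      for (s in names(cl_by)) {
        i <- cl_by[[s]]
        st <- floor(stats::runif(length(i), 1, max_start[i] + 1))
        en <- st + w[i] - 1
        rs <- starts[[s]]
        if (is.null(rs)) next
        re <- ends[[s]]
        # interval [st, en] overlaps some reference interval iff the last
        # reference start <= en has its end >= st
        k <- findInterval(en, rs)
        hits <- hits + sum(k >= 1 & re[pmax(k, 1)] >= st)
      }
      hits
    }, integer(1))
  })
  list(observed = observed, expected = mean(null_counts),
       p = (1 + sum(null_counts >= observed)) / (n_permutations + 1),
       n_permutations = as.integer(n_permutations))
}

#' Predict cis-natural antisense transcript genes
#'
#' A gene is a cis-NAT when its span overlaps a gene on the opposite strand
#' by at least one nucleotide; both partners are reported. The relation is
#' symmetric.
#'
#' @param gene_models `GRanges` of gene spans with strand and a `name`
#'   metadata column.
#' @return Character vector of cis-NAT gene names.
#' @export
predict_cis_nats <- function(gene_models) {
  if (length(gene_models) == 0) return(character(0))
  nm <- S4Vectors::mcols(gene_models)$name
  if (is.null(nm)) nm <- sprintf("gene_%d", seq_along(gene_models))
  str <- as.character(GenomicRanges::strand(gene_models))
  plus <- gene_models[str == "+"]
  minus <- gene_models[str == "-"]
  hits <- GenomicRanges::findOverlaps(plus, minus, ignore.strand = TRUE)
  sort(unique(c(nm[str == "+"][unique(S4Vectors::queryHits(hits))],
                nm[str == "-"][unique(S4Vectors::subjectHits(hits))])))
}

#' Fraction of cis-NAT genes and of cis-NAT-derived endo-siRNA clusters
#'
#' Reports (i) the fraction of gene models predicted to be cis-NATs and
#' (ii) among uniquely mapping endo-siRNA clusters that align to coding
#' genes (at least `min_fraction` of the cluster within a gene span), the
#' fraction whose gene is a cis-NAT.
#'
#' @param unique_endo_clusters Uniquely mapping endo-siRNA clusters
#'   (`GRanges`).
#' @param gene_models Gene spans (`GRanges` with `name`).
#' @param cis_nat_set Output of [predict_cis_nats()]; recomputed when `NULL`.
#' @param min_fraction Overlap fraction defining "aligns to a coding gene"
#'   (default 0.51, the genomic-context rule).
#' @return List: `gene_fraction`, `cluster_fraction` (both in `[0, 1]`),
#'   `n_genes`, `n_cis_nat`, `n_gene_clusters`, `n_cis_nat_clusters`.
#' @export
cis_nat_srna_fraction <- function(unique_endo_clusters, gene_models,
                                  cis_nat_set = NULL, min_fraction = 0.51) {
  if (is.null(cis_nat_set)) cis_nat_set <- predict_cis_nats(gene_models)
  n_genes <- length(gene_models)
  gene_fraction <- if (n_genes == 0) 0 else length(cis_nat_set) / n_genes

  nm <- S4Vectors::mcols(gene_models)$name
  if (is.null(nm)) nm <- sprintf("gene_%d", seq_along(gene_models))
  n_gene_cl <- 0L
  n_cis_cl <- 0L
  if (length(unique_endo_clusters) > 0 && n_genes > 0) {
    ov <- GenomicRanges::findOverlaps(unique_endo_clusters, gene_models,
                                      ignore.strand = TRUE)
    inter_w <- GenomicRanges::width(IRanges::pintersect(
      IRanges::ranges(unique_endo_clusters)[S4Vectors::queryHits(ov)],
      IRanges::ranges(gene_models)[S4Vectors::subjectHits(ov)]))
    frac <- inter_w /
      GenomicRanges::width(unique_endo_clusters)[S4Vectors::queryHits(ov)]
    keep <- frac >= min_fraction
    q <- S4Vectors::queryHits(ov)[keep]
    g <- nm[S4Vectors::subjectHits(ov)[keep]]
    aligned <- unique(q)
    n_gene_cl <- length(aligned)
    is_cis <- tapply(g %in% cis_nat_set, q, any)
    n_cis_cl <- sum(is_cis)
  }
  list(gene_fraction = gene_fraction,
       cluster_fraction = if (n_gene_cl == 0) 0 else n_cis_cl / n_gene_cl,
       n_genes = n_genes, n_cis_nat = length(cis_nat_set),
       n_gene_clusters = as.integer(n_gene_cl),
       n_cis_nat_clusters = as.integer(n_cis_cl))
}
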