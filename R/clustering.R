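#' Merge mapped reads into small RNA clusters
#'
#' Reads on the same scaffold are merged transitively (single linkage,
#' strand-agnostic) whenever the gap between their intervals is at most
#' `window` nucleotides; the default 150 bp window reflects the approximate
#' span of a long pre-miRNA so that products of one primary transcript fall
#' in one cluster. A merged locus is kept only if it contains at least
#' `min_distinct` distinct reads (distinct `(start, end, strand, sequence)`
#' tuples) that are not all perfectly overlapping (identical intervals), and
#' spans at least `min_cluster_len` bp.
#'
#' Each cluster records its total read abundance, the number of distinct
#' reads, the uniformity index `total_count / distinct_reads`, a read-length
#' histogram (length -> summed count), the strands contributing, whether any
#' constituent read is a multi-mapper, and back-references to the constituent
#' read records. Results are independent of input read order.
#'
#' @param reads Mapped reads (`GRanges`).
#' @param window Maximum merge gap in nucleotides (default 150).
#' @param min_distinct Minimum distinct reads per cluster (default 3).
#' @param min_cluster_len Minimum cluster span in bp (default 51).
#' @return A `GRanges` of clusters with metadata columns `cluster_id`,
#'   `total_count`, `distinct_reads`, `ui`, `length_hist` (an
#'   [IRanges::IntegerList] named by read length), `strands`,
#'   `multi_mapping` and `read_idx` (indices into the *sorted* read set,
#'   returned as attribute `reads`).
#' @export
build_clusters <- function(reads, window = 150L, min_distinct = 3L,
                           min_cluster_len = 51L) {
  if (window < 0L) stop_srna("window must be >= 0")
  out <- empty_clusters()
  if (length(reads) == 0) return(out)

  # canonical order makes clustering independent of input order
  mc0 <- S4Vectors::mcols(reads)
  o <- order(as.character(GenomicRanges::seqnames(reads)),
             GenomicRanges::start(reads), GenomicRanges::end(reads),
             as.character(GenomicRanges::strand(reads)), mc0$sequence)
  reads <- reads[o]
  mc <- S4Vectors::mcols(reads)

  loci <- GenomicRanges::reduce(GenomicRanges::granges(reads),
                                min.gapwidth = window + 1L,
                                ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(reads, loci, ignore.strand = TRUE)
  by_locus <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))

  keep <- logical(length(loci))
  stats <- vector("list", length(loci))
  for (k in seq_along(by_locus)) {
    i <- by_locus[[k]]
    li <- as.integer(names(by_locus)[k])
    key <- paste(GenomicRanges::start(reads)[i], GenomicRanges::end(reads)[i],
                 as.character(GenomicRanges::strand(reads))[i],
                 mc$sequence[i], sep = "\r")
    first <- !duplicated(key)
    n_distinct <- sum(first)
    ikey <- paste(GenomicRanges::start(reads)[i],
                  GenomicRanges::end(reads)[i], sep = "\r")
    # the non-perfect-overlap requirement accompanies the distinct-read
    # minimum; a single-read cluster allowed by min_distinct = 1 stands
    non_perfect <- min_distinct < 2L || length(unique(ikey)) >= 2L
    span <- GenomicRanges::width(loci)[li]
    if (n_distinct < min_distinct || !non_perfect || span < min_cluster_len) {
      next
    }
    keep[li] <- TRUE
    counts <- mc$count[i]
    lens <- nchar(mc$sequence[i])
    hist <- tapply(counts, lens, sum)
    stats[[li]] <- list(
      total_count = sum(counts),
      distinct_reads = n_distinct,
      length_hist = stats::setNames(as.integer(hist), names(hist)),
      strands = paste(sort(unique(
        as.character(GenomicRanges::strand(reads))[i])), collapse = ""),
      multi_mapping = any(mc$n_mappings[i] > 1L),
      read_idx = i
    )
  }

  cl <- loci[keep]
  st <- stats[keep]
  if (length(cl) == 0) return(out)
  total_count <- vapply(st, `[[`, numeric(1), "total_count")
  distinct_reads <- vapply(st, `[[`, numeric(1), "distinct_reads")
  S4Vectors::mcols(cl) <- S4Vectors::DataFrame(
    cluster_id = sprintf("cl%05d", seq_along(cl)),
    total_count = as.integer(total_count),
    distinct_reads = as.integer(distinct_reads),
    ui = total_count / distinct_reads,
    length_hist = IRanges::IntegerList(lapply(st, `[[`, "length_hist")),
    strands = vapply(st, `[[`, character(1), "strands"),
    multi_mapping = vapply(st, `[[`, logical(1), "multi_mapping"),
    read_idx = IRanges::IntegerList(lapply(st, `[[`, "read_idx"))
  )
  attr(cl, "reads") <- reads
  cl
}

empty_clusters <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    cluster_id = character(0), total_count = integer(0),
    distinct_reads = integer(0), ui = numeric(0),
    length_hist = IRanges::IntegerList(),
    strands = character(0), multi_mapping = logical(0),
    read_idx = IRanges::IntegerList()
  )
  gr
}

#' Uniformity index
#'
#' The ratio of the total abundance of small RNA reads comprising a cluster
#' to the number of distinct reads from that cluster. A miRNA-like locus with
#' 16 counts over three distinct reads scores 16/3 = 5.3; an endo-siRNA-like
#' locus with 16 counts over 12 distinct reads scores 16/12 = 1.3. The index
#' is always >= 1, with 1 meaning every distinct read is a singleton.
#'
#' @param clusters Clusters from [build_clusters()], or any `GRanges` with
#'   `total_count` and `distinct_reads` metadata columns.
#' @return Numeric vector of uniformity indices.
#' @export
compute_uniformity_index <- function(clusters) {
  mc <- S4Vectors::mcols(clusters)
  if (any(mc$distinct_reads == 0)) {
    stop_srna("uniformity index undefined for zero distinct reads")
  }
  as.numeric(mc$total_count) / as.numeric(mc$distinct_reads)
}

#' Depth-normalised uniformity index
#'
#' Raw uniformity indices grow with sequencing depth (deeper libraries pile
#' more copies onto the same dominant reads); dividing by the library depth
#' makes values comparable between libraries.
#'
#' @param ui Uniformity index (numeric vector).
#' @param library_depth Total mapped read count with each multi-mapping
#'   sequence counted once; see [library_depth()].
#' @return `ui / library_depth`.
#' @export
normalize_ui <- function(ui, library_depth) {
  if (length(library_depth) != 1 || library_depth <= 0) {
    stop_srna("library_depth must be a single positive number")
  }
  ui / library_depth
}

#' Partition clusters into high- and low-uniformity sets
#'
#' High-uniformity (HU) clusters -- miRNAs and other loci dominated by a few
#' abundant reads -- are separated from low-uniformity (LU) endo-siRNA and
#' piRNA clusters at a uniformity-index threshold.
#'
#' @param clusters Clusters with a `ui` metadata column.
#' @param threshold HU cut-off on the raw index (default 3); a cluster is HU
#'   when `ui >= threshold`.
#' @param quantile Optional alternative: when non-`NULL`, the threshold is the
#'   `1 - quantile` quantile of the observed index distribution (e.g.
#'   `quantile = 0.1` takes the top decile as HU), which is robust to library
#'   depth.
#' @return List with elements `hu` and `lu` (both `GRanges`) and the numeric
#'   `threshold` used.
#' @export
segregate_hu_lu <- function(clusters, threshold = 3, quantile = NULL) {
  if (!is.null(quantile)) {
    stopifnot(quantile > 0, quantile < 1)
    threshold <- stats::quantile(S4Vectors::mcols(clusters)$ui,
                                 probs = 1 - quantile, names = FALSE,
                                 type = 7)
  }
  if (threshold <= 1) stop_srna("HU threshold must exceed 1")
  hu <- S4Vectors::mcols(clusters)$ui >= threshold
  list(hu = clusters[hu], lu = clusters[!hu], threshold = threshold)
}
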