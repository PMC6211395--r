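#' Filter multi-mapping reads and extract the uniquely mapping subset
#'
#' Reads whose sequence maps to more than `max_mappings` genomic loci are
#' removed entirely (the classic 1-50 rule: a read seen 51 times is treated
#' as unmappable repeat-derived noise). A second, uniquely mapping subset
#' holds exactly the reads with a single genomic locus; downstream analyses
#' are run independently on both sets.
#'
#' @param reads Mapped reads (`GRanges` from [read_mapped_reads()]).
#' @param max_mappings Maximum tolerated mapping multiplicity (default 50).
#' @return A list of class `srna_filtered` with elements `all_reads`
#'   (1 <= n_mappings <= max_mappings) and `unique_reads` (n_mappings == 1).
#' @examples
#' r <- mapped_reads(rep("s", 3), c(0, 50, 90), c(21, 71, 111), "+",
#'                   strrep("ACGU", c(5, 5, 5)) |> paste0("A"),
#'                   count = c(3, 1, 1), n_mappings = c(1, 50, 51))
#' f <- filter_multimappers(r)
#' length(f$all_reads)     # the 51-locus read is gone
#' length(f$unique_reads)  # only the single-locus read
#' @export
filter_multimappers <- function(reads, max_mappings = 50L) {
  if (max_mappings < 1L) stop_srna("max_mappings must be >= 1")
  nm <- S4Vectors::mcols(reads)$n_mappings
  all_reads <- reads[nm <= max_mappings]
  unique_reads <- all_reads[S4Vectors::mcols(all_reads)$n_mappings == 1L]
  structure(list(all_reads = all_reads, unique_reads = unique_reads),
            class = "srna_filtered")
}

#' Remove reads overlapping annotated rRNA
#'
#' Any read whose mapping overlaps an rRNA interval by at least one
#' nucleotide is dropped before clustering. By default the overlap is
#' strand-agnostic (the most permissive removal); set `stranded = TRUE` to
#' remove only sense overlaps.
#'
#' @param reads Mapped reads.
#' @param rrna_track rRNA annotation (`GRanges`); may be empty.
#' @param stranded Require the read and rRNA interval to share a strand.
#' @return The reads with rRNA-overlapping mappings removed.
#' @export
exclude_rrna <- function(reads, rrna_track, stranded = FALSE) {
  if (length(rrna_track) == 0 || length(reads) == 0) return(reads)
  hits <- GenomicRanges::findOverlaps(reads, rrna_track,
                                      ignore.strand = !stranded)
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop) == 0) reads else reads[-drop]
}

#' Library depth for normalisation
#'
#' Total mapped read count with every multi-mapping sequence counted once:
#' the sum of `count` over distinct sequences.
#'
#' @param reads Mapped reads.
#' @return Integer depth.
#' @export
library_depth <- function(reads) {
  if (length(reads) == 0) return(0L)
  mc <- S4Vectors::mcols(reads)
  sum(mc$count[!duplicated(mc$sequence)])
}
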