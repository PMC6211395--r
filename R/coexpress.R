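#' Co-expression links between developmental stages
#'
#' Identifies genomic loci expressing an endo-siRNA or piRNA cluster in more
#' than one developmental library and emits one link per unordered stage
#' pair per locus -- the table behind a Circos co-expression plot. Cluster
#' spans from different stages are considered the same locus when they
#' overlap by at least one nucleotide; by default links require the same
#' cluster class in both stages.
#'
#' @param stage_clusters Named list of classified cluster `GRanges`, one per
#'   stage, on a shared coordinate system; list order defines the stage
#'   order used for canonical link orientation.
#' @param classes Cluster classes eligible for linking (default endo-siRNA
#'   and piRNA).
#' @param min_expression Minimum total read count in each stage (default 1).
#' @param class_matched Require the same class in both stages (default
#'   `TRUE`); when `FALSE`, any eligible class in either stage can link.
#' @return `data.frame` with columns `scaffold`, `start`, `end` (0-based
#'   half-open locus span), `class`, `stage_a`, `stage_b`, `count_a`,
#'   `count_b`; `stage_a` precedes `stage_b` in stage order. A cluster
#'   expressed in `k` stages yields `choose(k, 2)` links.
#' @export
coexpression_links <- function(stage_clusters,
                               classes = c("endo_siRNA", "piRNA"),
                               min_expression = 1L, class_matched = TRUE) {
  stages <- names(stage_clusters)
  if (is.null(stages) || any(stages == "")) {
    stop_srna("stage_clusters must be a named list")
  }
  empty <- data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), class = character(0),
                      stage_a = character(0), stage_b = character(0),
                      count_a = integer(0), count_b = integer(0),
                      stringsAsFactors = FALSE)
  link_groups <- if (class_matched) as.list(classes) else list(classes)
  rows <- list()
  for (grp in link_groups) {
    per_stage <- lapply(stage_clusters, function(cl) {
      lab <- as.character(S4Vectors::mcols(cl)$class)
      cl[!is.na(lab) & lab %in% grp &
           S4Vectors::mcols(cl)$total_count >= min_expression]
    })
    pooled <- unlist(GenomicRanges::GRangesList(lapply(per_stage,
                                                       GenomicRanges::granges)))
    if (length(pooled) == 0) next
    loci <- GenomicRanges::reduce(pooled, ignore.strand = TRUE)
    expr <- lapply(per_stage, function(cl) {
      ov <- GenomicRanges::findOverlaps(loci, cl, ignore.strand = TRUE)
      cnt <- tapply(S4Vectors::mcols(cl)$total_count[
        S4Vectors::subjectHits(ov)], S4Vectors::queryHits(ov), sum)
      out <- rep(0L, length(loci))
      out[as.integer(names(cnt))] <- as.integer(cnt)
      out
    })
    for (li in seq_along(loci)) {
      present <- stages[vapply(stages, function(s) expr[[s]][li] > 0,
                               logical(1))]
      if (length(present) < 2) next
      pairs <- utils::combn(present, 2)
      for (pi in seq_len(ncol(pairs))) {
        a <- pairs[1, pi]
        b <- pairs[2, pi]
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold = as.character(GenomicRanges::seqnames(loci)[li]),
          start = bed0_start(loci[li]),
          end = bed0_end(loci[li]),
          class = paste(grp, collapse = "|"),
          stage_a = a, stage_b = b,
          count_a = expr[[a]][li], count_b = expr[[b]][li],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$scaffold, out$start, out$class, out$stage_a, out$stage_b), ,
      drop = FALSE]
}

#' Restrict links to the largest scaffolds
#'
#' Keeps only links whose locus lies on one of the `top_n` longest scaffolds
#' (a Circos plot typically shows the ten largest).
#'
#' @param links Output of [coexpression_links()].
#' @param genome_lengths Named scaffold length vector.
#' @param top_n Number of scaffolds to keep (default 10).
#' @return The filtered link table.
#' @export
restrict_to_scaffolds <- function(links, genome_lengths, top_n = 10L) {
  keep_sc <- names(sort(genome_lengths, decreasing = TRUE))[
    seq_len(min(top_n, length(genome_lengths)))]
  links[links$scaffold %in% keep_sc, , drop = FALSE]
}
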