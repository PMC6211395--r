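#' Classification presets
#'
#' Read-length peak sets used to classify clusters. Dicer products (endo-
#' siRNAs) peak at 20-22 nt in all presets. piRNAs peak at 26-28 nt in the
#' non-bilaterian preset and at 24-26 nt in the Drosophila preset (piRNAs are
#' shorter in flies). The Mnemiopsis preset additionally recognises the
#' ctenophore-specific 25-mer class at 24-26 nt, which overlaps the piRNA
#' window at 26 nt; a cluster peaking at 26 nt is disambiguated by whichever
#' full peak set carries more summed read count, with ties going to piRNA.
#'
#' @param preset `"nonbilaterian"`, `"drosophila"` or `"mnemiopsis"`.
#' @param endo_peaks,pirna_peaks,mer25_peaks Override the preset peak sets.
#' @param apply_hu_filter Route high-uniformity Dicer-length clusters to
#'   `miRNA_candidate_HU` instead of `endo_siRNA` (default `TRUE`): HU
#'   clusters with 20-22 nt peaks are typically unannotated miRNAs, snoRNA/
#'   tRNA fragments or hairpin RNAs rather than true endo-siRNA loci.
#' @return A list of class `srna_class_config`.
#' @export
class_config <- function(preset = c("nonbilaterian", "drosophila",
                                    "mnemiopsis"),
                         endo_peaks = NULL, pirna_peaks = NULL,
                         mer25_peaks = NULL, apply_hu_filter = TRUE) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    nonbilaterian = list(endo = 20:22, pirna = 26:28, mer25 = integer(0)),
    drosophila    = list(endo = 20:22, pirna = 24:26, mer25 = integer(0)),
    mnemiopsis    = list(endo = 20:22, pirna = 26:28, mer25 = 24:26)
  )
  cfg <- list(
    preset = preset,
    endo_peaks = as.integer(if (is.null(endo_peaks)) defaults$endo
                            else endo_peaks),
    pirna_peaks = as.integer(if (is.null(pirna_peaks)) defaults$pirna
                             else pirna_peaks),
    mer25_peaks = as.integer(if (is.null(mer25_peaks)) defaults$mer25
                             else mer25_peaks),
    apply_hu_filter = isTRUE(apply_hu_filter)
  )
  if (length(intersect(cfg$endo_peaks, cfg$pirna_peaks)) > 0) {
    stop_srna("endo and piRNA peak sets must be disjoint")
  }
  class(cfg) <- "srna_class_config"
  cfg
}

#' Modal read length of a cluster
#'
#' The length with the largest summed read count; ties break toward the
#' shorter length so results are deterministic.
#'
#' @param length_histogram Named integer vector (length -> summed count).
#' @return Integer modal length.
#' @export
peak_length <- function(length_histogram) {
  if (length(length_histogram) == 0) {
    stop_srna("peak_length needs a non-empty histogram")
  }
  lens <- as.integer(names(length_histogram))
  o <- order(lens)
  lens <- lens[o]
  cnt <- as.numeric(length_histogram)[o]
  lens[which.max(cnt)]
}

#' Annotate clusters overlapping known loci
#'
#' Clusters overlapping a known miRNA hairpin, predicted tRNA or snoRNA by at
#' least one nucleotide are labelled accordingly (precedence
#' known_miRNA > tRNA > snoRNA) and bypass the read-length classifier.
#'
#' @param clusters Clusters (`GRanges`).
#' @param tracks Named list of annotation `GRanges`; entries `known_miRNA`,
#'   `tRNA` and `snoRNA` are consulted, any may be absent or empty.
#' @return `clusters` with a `class` metadata column (`NA` where no known
#'   locus overlaps).
#' @export
annotate_known_loci <- function(clusters, tracks = list()) {
  lab <- rep(NA_character_, length(clusters))
  for (cls in c("snoRNA", "tRNA", "known_miRNA")) {  # ascending precedence
    trk <- tracks[[cls]]
    if (is.null(trk) || length(trk) == 0) next
    hit <- GenomicRanges::countOverlaps(clusters, trk,
                                        ignore.strand = TRUE) > 0
    lab[hit] <- cls
  }
  S4Vectors::mcols(clusters)$class <- lab
  clusters
}

#' Classify one length histogram by its read-length peak
#'
#' Implements the peak-dominance rule: let `L` be the modal read length; the
#' cluster is assigned to a class whose peak set contains `L` only when the
#' summed count at `L - 1 .. L + 1` is strictly greater than the summed count
#' of all other size classes. Dicer-length peaks (`endo_peaks`) yield
#' `endo_siRNA` -- or `miRNA_candidate_HU` when the cluster is high
#' uniformity and the HU filter is active. Anything else is `unclassified`.
#'
#' @param length_histogram Named integer vector (length -> summed count).
#' @param config A [class_config()].
#' @param is_hu Is the cluster high-uniformity?
#' @return A single class label string.
#' @export
classify_by_peak <- function(length_histogram, config, is_hu = FALSE) {
  L <- peak_length(length_histogram)
  lens <- as.integer(names(length_histogram))
  cnt <- as.numeric(length_histogram)
  halo <- sum(cnt[lens >= L - 1L & lens <= L + 1L])
  others <- sum(cnt) - halo
  if (!(halo > others)) return("unclassified")

  in_endo <- L %in% config$endo_peaks
  in_pirna <- L %in% config$pirna_peaks
  in_mer25 <- L %in% config$mer25_peaks
  if (in_endo) {
    if (is_hu && config$apply_hu_filter) return("miRNA_candidate_HU")
    return("endo_siRNA")
  }
  if (in_pirna && in_mer25) {
    # ambiguous peak (Mnemiopsis, 26 nt): the peak set holding more summed
    # count wins; ties go to piRNA
    s_pi <- sum(cnt[lens %in% config$pirna_peaks])
    s_25 <- sum(cnt[lens %in% config$mer25_peaks])
    return(if (s_25 > s_pi) "mer25" else "piRNA")
  }
  if (in_pirna) return("piRNA")
  if (in_mer25) return("mer25")
  "unclassified"
}

#' Classify all clusters
#'
#' Runs [annotate_known_loci()] and then the read-length peak classifier on
#' the remaining clusters, using the cluster uniformity index against
#' `hu_threshold` for the HU routing.
#'
#' @param clusters Clusters from [build_clusters()].
#' @param tracks Named list of annotation tracks (see
#'   [annotate_known_loci()]).
#' @param config A [class_config()].
#' @param hu_threshold Uniformity-index threshold for HU status (default 3).
#' @return `clusters` with a completed `class` metadata column; labels are
#'   mutually exclusive and exhaustive (`unclassified` is the catch-all).
#' @export
classify_clusters <- function(clusters, tracks = list(),
                              config = class_config(), hu_threshold = 3) {
  clusters <- annotate_known_loci(clusters, tracks)
  lab <- S4Vectors::mcols(clusters)$class
  ui <- S4Vectors::mcols(clusters)$ui
  hist_list <- as.list(S4Vectors::mcols(clusters)$length_hist)
  todo <- which(is.na(lab))
  for (i in todo) {
    lab[i] <- classify_by_peak(hist_list[[i]], config,
                               is_hu = ui[i] >= hu_threshold)
  }
  S4Vectors::mcols(clusters)$class <- factor(lab, levels = CLASS_LABELS)
  S4Vectors::mcols(clusters)$peak_length <-
    vapply(hist_list, peak_length, integer(1))
  clusters
}

#' Tabulate cluster classes per library
#'
#' Produces the per-library summary of annotated cluster counts: miRNA
#' clusters, then endo-siRNA and piRNA clusters split into uniquely mapping
#' and multi-mapping (a multi-mapping cluster contains at least one read with
#' more than one genomic mapping). Counts for the ctenophore 25-mer class are
#' appended when present.
#'
#' @param classified Named list (one element per library) of classified
#'   cluster `GRanges`.
#' @return A `data.frame`, one row per library.
#' @export
tabulate_classes <- function(classified) {
  if (inherits(classified, "GRanges")) classified <- list(library = classified)
  rows <- lapply(names(classified), function(nm) {
    cl <- classified[[nm]]
    lab <- as.character(S4Vectors::mcols(cl)$class)
    multi <- S4Vectors::mcols(cl)$multi_mapping
    if (length(cl) == 0) multi <- logical(0)
    cnt <- function(class, mm = NULL) {
      sel <- lab == class
      if (!is.null(mm)) sel <- sel & (multi == mm)
      sum(sel, na.rm = TRUE)
    }
    data.frame(
      library = nm,
      miRNA = cnt("known_miRNA"),
      miRNA_candidate_HU = cnt("miRNA_candidate_HU"),
      unique_endo_siRNA = cnt("endo_siRNA", FALSE),
      multi_endo_siRNA = cnt("endo_siRNA", TRUE),
      unique_piRNA = cnt("piRNA", FALSE),
      multi_piRNA = cnt("piRNA", TRUE),
      unique_mer25 = cnt("mer25", FALSE),
      multi_mer25 = cnt("mer25", TRUE),
      unclassified = cnt("unclassified"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
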