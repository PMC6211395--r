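#' Read mapped small-RNA reads
#'
#' Reads one genomic mapping per row. The native format is a BED-like TSV with
#' a header line and columns `scaffold`, `start`, `end` (0-based half-open),
#' `strand`, `sequence`, `count` (abundance of the collapsed sequence in the
#' library) and `n_mappings` (number of genomic loci the sequence maps to).
#' SAM input is also accepted: mapping multiplicity is taken from the `NH` tag
#' and abundance from a trailing `_xN` suffix on the query name (the usual
#' read-collapser convention), defaulting to 1.
#'
#' @param path Path to the reads file.
#' @param format `"tsv"` (default) or `"sam"`.
#' @return A [GenomicRanges::GRanges] with metadata columns `sequence`
#'   (uppercase RNA alphabet), `count` and `n_mappings`. Coordinates are
#'   1-based closed internally; widths equal sequence lengths.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("scaffold\tstart\tend\tstrand\tsequence\tcount\tn_mappings",
#'              "chr1\t100\t121\t+\tUGAGGUAGUAGGUUGUAUAGU\t7\t1"), tf)
#' read_mapped_reads(tf)
#' @export
read_mapped_reads <- function(path, format = c("tsv", "sam")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_srna("reads file not found: %s", path)
  if (format == "sam") return(read_mapped_reads_sam(path))

  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("scaffold", "start", "end", "strand", "sequence",
                "count", "n_mappings")
  missing <- setdiff(required, colnames(df))
  if (length(missing) > 0) {
    stop_srna("reads file %s lacks column(s): %s", path,
              paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) return(empty_mapped_reads())

  start0 <- suppressWarnings(as.integer(df$start))
  end0 <- suppressWarnings(as.integer(df$end))
  count <- suppressWarnings(as.integer(df$count))
  nmap <- suppressWarnings(as.integer(df$n_mappings))
  # +1 for the header line so errors point at the file line
  bad <- which(is.na(start0) | is.na(end0) | is.na(count) | is.na(nmap))
  if (length(bad) > 0) {
    stop_srna("malformed numeric field at line %d of %s", bad[1] + 1L, path)
  }
  bad <- which(start0 < 0)
  if (length(bad) > 0) {
    stop_srna("negative coordinate at line %d of %s", bad[1] + 1L, path)
  }
  mapped_reads(df$scaffold, start0, end0, df$strand, df$sequence,
               count, nmap, source = path)
}

read_mapped_reads_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop_srna("SAM input requires the Rsamtools package")
  }
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "seq"),
    tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  if (length(x$pos) == 0) return(empty_mapped_reads())
  seqs <- as.character(x$seq)
  # SAM stores the reverse complement for minus-strand alignments; recover
  # the read as sequenced so stored sequences are 5'->3' of the small RNA
  minus <- as.character(x$strand) == "-"
  if (any(minus)) {
    seqs[minus] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[minus])))
  }
  counts <- sub_count_from_qname(x$qname)
  nh <- x$tag$NH
  if (is.null(nh)) nh <- rep(1L, length(seqs))
  nh[is.na(nh)] <- 1L
  start0 <- x$pos - 1L
  mapped_reads(as.character(x$rname), start0, start0 + nchar(seqs),
               as.character(x$strand), seqs, counts, nh, source = path)
}

sub_count_from_qname <- function(qname) {
  m <- regmatches(qname, regexpr("_x([0-9]+)$", qname))
  out <- rep(1L, length(qname))
  has <- nchar(m) > 0
  out[has] <- as.integer(sub("_x", "", m[has]))
  out
}

empty_mapped_reads <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(sequence = character(0),
                                               count = integer(0),
                                               n_mappings = integer(0))
  gr
}

#' Construct a set of mapped reads
#'
#' Validates the mapped-read invariants (interval width equals sequence
#' length, `count >= 1`, `n_mappings >= 1`) and returns the internal
#' representation used throughout the package.
#'
#' @param scaffold,start0,end0,strand Per-mapping location (0-based half-open
#'   input coordinates).
#' @param sequence Read sequence; `T`/`U` are equivalent on input.
#' @param count Library abundance of the collapsed sequence (shared by all of
#'   its mappings).
#' @param n_mappings Number of genomic loci the sequence maps to.
#' @param source Optional label used in error messages.
#' @return A `GRanges` of mapped reads.
#' @export
mapped_reads <- function(scaffold, start0, end0, strand, sequence,
                         count, n_mappings, source = "input") {
  sequence <- normalize_rna(sequence)
  n <- length(scaffold)
  stopifnot(length(start0) == n, length(end0) == n, length(sequence) == n)
  bad <- which(end0 - start0 != nchar(sequence))
  if (length(bad) > 0) {
    stop_srna("%s line %d: sequence length %d does not match interval %d-%d",
              source, bad[1] + 1L, nchar(sequence[bad[1]]),
              start0[bad[1]], end0[bad[1]])
  }
  bad <- which(count < 1L)
  if (length(bad) > 0) {
    stop_srna("%s line %d: count must be >= 1", source, bad[1] + 1L)
  }
  bad <- which(n_mappings < 1L)
  if (length(bad) > 0) {
    stop_srna("%s line %d: n_mappings must be >= 1", source, bad[1] + 1L)
  }
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad) > 0) {
    stop_srna("%s line %d: strand must be '+' or '-'", source, bad[1] + 1L)
  }
  gr <- gr_from_bed0(scaffold, start0, end0, strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    sequence = sequence,
    count = as.integer(count),
    n_mappings = as.integer(n_mappings)
  )
  gr
}

#' Write mapped reads to the native TSV format
#'
#' Inverse of [read_mapped_reads()]; `read_mapped_reads(write_mapped_reads(x))`
#' reproduces every field.
#'
#' @param reads Mapped reads (`GRanges`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mapped_reads <- function(reads, path) {
  df <- data.frame(
    scaffold = as.character(GenomicRanges::seqnames(reads)),
    start = bed0_start(reads),
    end = bed0_end(reads),
    strand = as.character(GenomicRanges::strand(reads)),
    sequence = S4Vectors::mcols(reads)$sequence,
    count = S4Vectors::mcols(reads)$count,
    n_mappings = S4Vectors::mcols(reads)$n_mappings,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an annotation track
#'
#' Imports a BED or GFF/GTF file as one genomic element class. GFF's 1-based
#' inclusive coordinates and BED's 0-based half-open coordinates are both
#' normalised to the internal convention, so a GFF exon at `101..200` and a
#' BED exon at `100 200` yield the same interval. Overlapping intervals are
#' preserved, not merged.
#'
#' @param path Path to the track file.
#' @param element_class One of `"exon"`, `"intron"`, `"utr5"`, `"utr3"`,
#'   `"transposon_known"`, `"transposon_unknown"`, `"rRNA"`, `"tRNA"`,
#'   `"snoRNA"`, `"known_miRNA"`, `"gene_model"`.
#' @param format `"bed"` or `"gff"`; guessed from the extension when `NULL`.
#' @return A `GRanges`; the element class is stored in
#'   `S4Vectors::metadata(x)$element_class`.
#' @export
read_annotation <- function(path, element_class, format = NULL) {
  if (!element_class %in% ELEMENT_CLASSES) {
    stop_srna("unknown element_class '%s'; expected one of: %s",
              element_class, paste(ELEMENT_CLASSES, collapse = ", "))
  }
  if (!file.exists(path)) stop_srna("annotation file not found: %s", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gff", "gff3", "gtf")) "gff" else "bed"
  }
  gr <- rtracklayer::import(path, format = format)
  gr <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr),
    ranges = IRanges::ranges(gr),
    strand = GenomicRanges::strand(gr),
    name = track_names(gr, element_class)
  )
  S4Vectors::metadata(gr)$element_class <- element_class
  gr
}

track_names <- function(gr, prefix) {
  mc <- S4Vectors::mcols(gr)
  nm <- if ("name" %in% colnames(mc)) as.character(mc$name)
        else if ("ID" %in% colnames(mc)) as.character(mc$ID)
        else rep(NA_character_, length(gr))
  idx <- which(is.na(nm) | nm == "")
  nm[idx] <- sprintf("%s_%d", prefix, idx)
  nm
}

#' Build an annotation track from coordinates
#'
#' Programmatic counterpart of [read_annotation()], used by the simulator and
#' convenient in tests.
#'
#' @inheritParams mapped_reads
#' @param element_class See [read_annotation()].
#' @param name Optional interval names.
#' @return A `GRanges` track.
#' @export
annotation_track <- function(scaffold, start0, end0, strand = "*",
                             element_class = "exon", name = NULL) {
  if (!element_class %in% ELEMENT_CLASSES) {
    stop_srna("unknown element_class '%s'", element_class)
  }
  if (any(start0 >= end0)) stop_srna("track intervals need start < end")
  gr <- gr_from_bed0(scaffold, start0, end0, strand)
  if (is.null(name)) name <- sprintf("%s_%d", element_class, seq_along(gr))
  S4Vectors::mcols(gr)$name <- name
  S4Vectors::metadata(gr)$element_class <- element_class
  gr
}

#' Read a genome FASTA
#'
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet]; record names are truncated at the
#'   first whitespace.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write the per-cluster report
#'
#' One row per cluster: location, class label, uniformity index (raw and
#' depth-normalised), modal read length, abundance, distinct reads, genomic
#' context and fold results. Columns absent from the cluster object (for
#' example fold results before the structure stage has run) are emitted as
#' `NA`. The serialized length histogram column allows a written report to be
#' re-read losslessly with [read_cluster_report()].
#'
#' @param clusters Classified clusters (`GRanges` from [build_clusters()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(clusters, path) {
  mc <- S4Vectors::mcols(clusters)
  pick <- function(col, default = NA) {
    if (col %in% colnames(mc)) mc[[col]] else rep(default, length(clusters))
  }
  hist_ser <- vapply(seq_along(clusters), function(i) {
    h <- as.list(mc$length_hist)[[i]]
    paste(sprintf("%s:%d", names(h), as.integer(h)), collapse = ",")
  }, character(1))
  df <- data.frame(
    scaffold = as.character(GenomicRanges::seqnames(clusters)),
    start = bed0_start(clusters),
    end = bed0_end(clusters),
    cluster_id = pick("cluster_id", NA_character_),
    class = as.character(pick("class", NA_character_)),
    ui = fmt_num(pick("ui"), 10),
    ui_normalized = fmt_num(pick("ui_normalized"), 10),
    peak_length = pick("peak_length", NA_integer_),
    total_count = pick("total_count", NA_integer_),
    distinct_reads = pick("distinct_reads", NA_integer_),
    multi_mapping = pick("multi_mapping", NA),
    strands = pick("strands", NA_character_),
    context = as.character(pick("context", NA_character_)),
    fold_strand = as.character(pick("fold_strand", NA_character_)),
    mfe = fmt_num(pick("mfe"), 10),
    randfold_p = fmt_num(pick("randfold_p"), 10),
    length_hist = hist_ser,
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Re-read a written cluster report
#'
#' @param path Path produced by [write_cluster_report()].
#' @return Clusters as a `GRanges` with the report columns as metadata.
#' @export
read_cluster_report <- function(path) {
  if (!file.exists(path)) stop_srna("cluster report not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          na.strings = "NA")
  gr <- gr_from_bed0(df$scaffold, df$start, df$end)
  hist_list <- lapply(df$length_hist, function(s) {
    if (is.na(s) || s == "") return(integer(0))
    parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    stats::setNames(vapply(parts, function(p) as.integer(p[2]), integer(1)),
                    vapply(parts, `[`, character(1), 1))
  })
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    cluster_id = df$cluster_id,
    class = df$class,
    ui = as.numeric(df$ui),
    ui_normalized = as.numeric(df$ui_normalized),
    peak_length = df$peak_length,
    total_count = df$total_count,
    distinct_reads = df$distinct_reads,
    multi_mapping = df$multi_mapping,
    strands = df$strands,
    context = df$context,
    fold_strand = df$fold_strand,
    mfe = as.numeric(df$mfe),
    randfold_p = as.numeric(df$randfold_p),
    length_hist = IRanges::IntegerList(hist_list)
  )
  gr
}
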