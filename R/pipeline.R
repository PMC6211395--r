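PIPELINE_DEFAULTS <- list(
  window = 150L, min_distinct = 3L, min_cluster_len = 51L,
  max_mappings = 50L, hu_threshold = 3, preset = "nonbilaterian",
  n_shuffles = 100L, local_span = 150L, fold_backend = "builtin",
  min_fraction = 0.51, u1_min = 40, a10_min = 35,
  dg_from = 25L, dg_factor = 1.25, min_expression = 1L,
  top_scaffolds = 0L, rrna_stranded = FALSE, seed = 1L,
  out_dir = "srnaclust_out"
)

#' Pipeline configuration
#'
#' Collects every stage parameter with its default. Path entries (`reads`,
#' `genome`, `annot`) may be omitted when the corresponding objects are
#' passed to [run_pipeline()] directly.
#'
#' @param reads Named character vector of reads-file paths (one per
#'   library).
#' @param genome Genome FASTA path.
#' @param annot Named character vector of annotation paths, names being
#'   element classes.
#' @param ... Parameter overrides; see `srnaclust:::PIPELINE_DEFAULTS` for
#'   names and defaults. Unknown names are rejected.
#' @return A list of class `srna_config`.
#' @export
pipeline_config <- function(reads = character(0), genome = NULL,
                            annot = character(0), ...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(PIPELINE_DEFAULTS))
  if (length(unknown) > 0) {
    stop_srna("unknown configuration key(s): %s",
              paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, over)
  cfg$reads <- reads
  cfg$genome <- genome
  cfg$annot <- annot
  class(cfg) <- "srna_config"
  cfg
}

#' Read a pipeline configuration file
#'
#' Plain-text `key = value` format, one pair per line, `#` comments.
#' Library reads are given as `reads.<name> = <path>` and annotations as
#' `annot.<element_class> = <path>`; all other keys are the parameters of
#' [pipeline_config()]. Unknown keys are rejected.
#'
#' @param path Config file path.
#' @return An `srna_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_srna("config file not found: %s", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- which(lengths(kv) != 3)
  if (length(bad) > 0) {
    stop_srna("malformed config line: '%s'", lines[bad[1]])
  }
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- trimws(vapply(kv, `[`, character(1), 3))
  reads <- character(0)
  annot <- character(0)
  genome <- NULL
  over <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    v <- vals[i]
    if (startsWith(k, "reads.")) {
      reads[sub("^reads\\.", "", k)] <- v
    } else if (startsWith(k, "annot.")) {
      cls <- sub("^annot\\.", "", k)
      if (!cls %in% ELEMENT_CLASSES) {
        stop_srna("unknown annotation class in config: %s", cls)
      }
      annot[cls] <- v
    } else if (k == "genome") {
      genome <- v
    } else if (k %in% names(PIPELINE_DEFAULTS)) {
      proto <- PIPELINE_DEFAULTS[[k]]
      over[[k]] <- if (is.logical(proto)) as.logical(v)
                   else if (is.numeric(proto)) as.numeric(v)
                   else v
    } else {
      stop_srna("unknown configuration key: %s", k)
    }
  }
  do.call(pipeline_config,
          c(list(reads = reads, genome = genome, annot = annot), over))
}

#' Write a pipeline configuration file
#'
#' @param config An `srna_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  lines <- character(0)
  for (nm in names(config$reads)) {
    lines <- c(lines, sprintf("reads.%s = %s", nm, config$reads[[nm]]))
  }
  if (!is.null(config$genome)) {
    lines <- c(lines, sprintf("genome = %s", config$genome))
  }
  for (nm in names(config$annot)) {
    lines <- c(lines, sprintf("annot.%s = %s", nm, config$annot[[nm]]))
  }
  for (nm in names(PIPELINE_DEFAULTS)) {
    lines <- c(lines, sprintf("%s = %s", nm, as.character(config[[nm]])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Run the full annotation pipeline
#'
#' Orchestrates every stage for one or more libraries: multimapper
#' filtering (all-reads and unique-reads tracks are processed
#' independently), rRNA exclusion, clustering, uniformity-index computation
#' and normalisation, class annotation, positional-bias signatures,
#' strand-resolved folding with the shuffle significance test, genomic
#' context attribution, cis-NAT prediction and cross-library co-expression
#' links. All stage outputs are written to `config$out_dir` as plain TSV so
#' any stage can be inspected or re-entered.
#'
#' @param config An `srna_config` (or path to a config file).
#' @param reads Optional named list of mapped-read `GRanges`, bypassing
#'   `config$reads` paths.
#' @param genome Optional `DNAStringSet`, bypassing `config$genome`.
#' @param tracks Optional named list of annotation `GRanges`, bypassing
#'   `config$annot`.
#' @return Invisibly, a list with the per-library classified clusters
#'   (`clusters`), `class_table`, `signatures`, `structure_curves`,
#'   `context_summary`, `genome_coverage`, `links`, `cisnat` and the vector
#'   of written `files`.
#' @export
run_pipeline <- function(config, reads = NULL, genome = NULL,
                         tracks = NULL) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "srna_config"))
  if (!config$preset %in% c("nonbilaterian", "drosophila", "mnemiopsis")) {
    stop_srna("invalid preset '%s' (flag: preset)", config$preset)
  }
  if (is.null(reads)) {
    if (length(config$reads) == 0) stop_srna("stage input: no reads given")
    reads <- lapply(config$reads, read_mapped_reads)
  }
  if (is.null(genome)) {
    if (is.null(config$genome)) stop_srna("stage input: no genome given")
    genome <- read_genome(config$genome)
  }
  if (is.null(tracks)) {
    tracks <- lapply(names(config$annot), function(cls) {
      read_annotation(config$annot[[cls]], cls)
    })
    names(tracks) <- names(config$annot)
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, path)
    path
  }
  log_msg <- function(fmt, ...) {
    message(sprintf(paste0("[srnaclust] ", fmt), ...))
  }
  cfg_class <- class_config(config$preset)
  genome_lengths <- stats::setNames(as.numeric(Biostrings::width(genome)),
                                    names(genome))
  log_msg("parameters: window=%d min_distinct=%d min_cluster_len=%d %s",
          config$window, config$min_distinct, config$min_cluster_len,
          sprintf("max_mappings=%d hu=%.3g preset=%s shuffles=%d seed=%d",
                  config$max_mappings, config$hu_threshold, config$preset,
                  config$n_shuffles, config$seed))

  clusters <- list()
  signature_rows <- list()
  lib_i <- 0L
  for (lib in names(reads)) {
    lib_i <- lib_i + 1L
    filt <- filter_multimappers(reads[[lib]], config$max_mappings)
    for (subset in c("all", "unique")) {
      rd <- if (subset == "all") filt$all_reads else filt$unique_reads
      rd <- exclude_rrna(rd, tracks[["rRNA"]],
                         stranded = isTRUE(config$rrna_stranded))
      depth <- library_depth(rd)
      cl <- build_clusters(rd, config$window, config$min_distinct,
                           config$min_cluster_len)
      if (length(cl) > 0 && depth > 0) {
        S4Vectors::mcols(cl)$ui_normalized <-
          normalize_ui(S4Vectors::mcols(cl)$ui, depth)
      }
      cl <- classify_clusters(cl, tracks, cfg_class, config$hu_threshold)
      if (subset == "all" && length(cl) > 0) {
        cl <- fold_clusters(cl, genome, config$n_shuffles,
                            rng_seed = config$seed + 1000L * lib_i,
                            local_span = config$local_span,
                            backend = config$fold_backend)
      }
      masked <- mask_genic_by_transposon(tracks)
      if (length(cl) > 0) {
        asg <- assign_context(cl, masked, config$min_fraction)
        S4Vectors::mcols(cl)$context <- asg$contexts
        attr(cl, "context_assignment") <- asg
      }
      clusters[[paste(lib, subset, sep = ":")]] <- cl
      files <- c(files, write_cluster_report(
        cl, file.path(out_dir, sprintf("clusters_%s_%s.tsv", lib, subset))))
      log_msg("%s/%s: %d reads, depth %d, %d clusters", lib, subset,
              length(rd), depth, length(cl))

      if (subset == "all" && length(cl) > 0) {
        srt_reads <- attr(cl, "reads")
        for (cls in c("endo_siRNA", "piRNA", "mer25")) {
          sel <- which(as.character(S4Vectors::mcols(cl)$class) == cls)
          if (length(sel) == 0) next
          idx <- unique(unlist(as.list(
            S4Vectors::mcols(cl)$read_idx[sel])))
          bias <- positional_bias(srt_reads[idx])
          files <- c(files, write_bias_matrix(
            bias, file.path(out_dir, sprintf("bias_%s_%s.tsv", lib, cls))))
          pp <- detect_ping_pong(bias, config$u1_min, config$a10_min)
          u5 <- detect_5prime_u(bias, config$u1_min)
          dg <- detect_downstream_g(bias, config$dg_from, config$dg_factor)
          signature_rows[[length(signature_rows) + 1L]] <- data.frame(
            library = lib, class = cls,
            u1_pct = round(pp$u1, 2), a10_pct = round(pp$a10, 2),
            ping_pong = pp$positive, five_prime_u = u5$positive,
            downstream_g = dg$status,
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  class_table <- tabulate_classes(clusters)
  emit(class_table, "class_table.tsv")
  signatures <- if (length(signature_rows) > 0) {
    do.call(rbind, signature_rows)
  } else {
    data.frame(library = character(0), class = character(0))
  }
  emit(signatures, "signatures.tsv")

  all_cl <- clusters[grepl(":all$", names(clusters))]
  pooled <- all_cl[[1]]
  if (length(all_cl) > 1) {
    for (k in 2:length(all_cl)) {
      pooled <- suppressWarnings(c(pooled, all_cl[[k]]))
    }
  }
  curves <- if (length(pooled) > 0) {
    structure_enrichment_curves(pooled)
  } else {
    data.frame(class = character(0), cutoff = numeric(0),
               percent = numeric(0), n = integer(0))
  }
  emit(curves, "structure_curves.tsv")

  ctx <- do.call(rbind, lapply(names(all_cl), function(nm) {
    cl <- all_cl[[nm]]
    if (length(cl) == 0) return(NULL)
    cbind(library = sub(":all$", "", nm),
          context_summary(cl, attr(cl, "context_assignment")))
  }))
  if (is.null(ctx)) {
    ctx <- data.frame(library = character(0), class = character(0),
                      element_class = character(0), percent = numeric(0))
  }
  emit(ctx, "context_summary.tsv")
  emit(genome_coverage(tracks[!vapply(tracks, is.null, logical(1))],
                       genome_lengths), "genome_coverage.tsv")

  cisnat <- data.frame(n_genes = 0L, n_cis_nat = 0L, gene_pct = NA_real_,
                       n_gene_clusters = 0L, n_cis_nat_clusters = 0L,
                       cluster_pct = NA_real_)
  gm <- tracks[["gene_model"]]
  if (!is.null(gm) && length(gm) > 0) {
    uniq_cl <- clusters[grepl(":unique$", names(clusters))]
    uniq_endo <- NULL
    for (cl in uniq_cl) {
      sel <- as.character(S4Vectors::mcols(cl)$class) == "endo_siRNA"
      g <- GenomicRanges::granges(cl[sel])
      uniq_endo <- if (is.null(uniq_endo)) g
                   else suppressWarnings(c(uniq_endo, g))
    }
    if (is.null(uniq_endo)) uniq_endo <- GenomicRanges::GRanges()
    cn <- cis_nat_srna_fraction(uniq_endo, gm,
                                min_fraction = config$min_fraction)
    cisnat <- data.frame(n_genes = cn$n_genes, n_cis_nat = cn$n_cis_nat,
                         gene_pct = round(100 * cn$gene_fraction, 1),
                         n_gene_clusters = cn$n_gene_clusters,
                         n_cis_nat_clusters = cn$n_cis_nat_clusters,
                         cluster_pct = round(100 * cn$cluster_fraction, 1))
  }
  emit(cisnat, "cisnat.tsv")

  stage_cl <- all_cl
  names(stage_cl) <- sub(":all$", "", names(stage_cl))
  links <- coexpression_links(stage_cl,
                              min_expression = config$min_expression)
  if (config$top_scaffolds > 0) {
    links <- restrict_to_scaffolds(links, genome_lengths,
                                   config$top_scaffolds)
  }
  emit(links, "links.tsv")
  write_config(config, file.path(out_dir, "run_config.txt"))
  log_msg("wrote %d report files to %s", length(files), out_dir)

  invisible(list(clusters = clusters, class_table = class_table,
                 signatures = signatures, structure_curves = curves,
                 context_summary = ctx, cisnat = cisnat, links = links,
                 files = files))
}
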