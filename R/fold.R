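#' Minimum free energy of a putative precursor
#'
#' Folds an RNA sequence and returns the minimum free energy and dot-bracket
#' structure, considering only base pairs whose span does not exceed
#' `local_span` (the locally stable structures relevant to a precursor
#' cassette). The folding engine is a pluggable contract:
#'
#' * `builtin` (default): weighted Nussinov base-pair maximisation with an
#'   energy proxy of -1 per GC, -0.7 per AU and -0.5 per GU pair, minimum
#'   hairpin loop of 3 nt. Deterministic and self-contained; used
#'   consistently for both native and shuffled sequences in
#'   [randfold_test()].
#' * `vienna`: ViennaRNA's `RNALfold` executable (full nearest-neighbour
#'   thermodynamics), when present on the `PATH`. The best local structure
#'   is reported padded to the full sequence length.
#'
#' @param sequence RNA (or DNA; `T` is read as `U`) sequence.
#' @param local_span Maximum base-pair span in nucleotides (default 150).
#' @param backend `"builtin"` or `"vienna"`.
#' @return List with `mfe` (kcal/mol-scaled proxy, `<= 0`; 0 when
#'   unstructured) and `structure` (dot-bracket string of the same length as
#'   the sequence).
#' @examples
#' fold_mfe("AAAAAAAAAA")$mfe   # 0: nothing can pair
#' fold_mfe(paste0(strrep("G", 10), "AAAA", strrep("C", 10)))
#' @export
fold_mfe <- function(sequence, local_span = 150L,
                     backend = c("builtin", "vienna")) {
  backend <- match.arg(backend)
  s <- normalize_rna(sequence)
  if (nchar(s) == 0) stop_srna("cannot fold an empty sequence")
  if (grepl("[^ACGU]", s)) {
    stop_srna("sequence contains a non-ACGU character")
  }
  if (backend == "vienna") return(fold_mfe_vienna(s, local_span))
  code <- match(strsplit(s, "", fixed = TRUE)[[1]],
                c("A", "C", "G", "U")) - 1L
  res <- .nussinov_fold_c(code, as.integer(local_span), 3L, 1.0, 0.7, 0.5)
  mfe <- -res$score
  if (mfe == 0) mfe <- 0  # normalise -0
  list(mfe = mfe, structure = res$structure)
}

fold_mfe_vienna <- function(s, local_span) {
  if (Sys.which("RNALfold") == "") {
    stop_srna("backend 'vienna' requires RNALfold on the PATH")
  }
  out <- suppressWarnings(system2(
    "RNALfold", args = c("-L", as.character(max(2L, as.integer(local_span)))),
    input = c(">q", s), stdout = TRUE, stderr = FALSE))
  pat <- "^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)\\s+([0-9]+)\\s*$"
  hits <- regmatches(out, regexec(pat, out))
  hits <- hits[lengths(hits) == 4]
  n <- nchar(s)
  if (length(hits) == 0) {
    return(list(mfe = 0, structure = strrep(".", n)))
  }
  en <- vapply(hits, function(h) as.numeric(h[3]), numeric(1))
  best <- hits[[which.min(en)]]
  db <- strrep(".", n)
  pos <- as.integer(best[4])
  substr(db, pos, pos + nchar(best[2]) - 1L) <- best[2]
  list(mfe = min(en), structure = db)
}

#' Strand-resolved fold of a cluster
#'
#' Extracts the cluster span from the genome and folds the putative
#' precursor. Clusters whose reads derive from one strand are folded on that
#' strand only; for mixed-strand clusters both strands are folded and the
#' lower minimum free energy is retained, with ties resolved to the plus
#' strand for reproducibility.
#'
#' @param cluster A single cluster (`GRanges` of length 1 with a `strands`
#'   metadata column; absent/`*` is treated as both strands).
#' @param genome A [Biostrings::DNAStringSet].
#' @inheritParams fold_mfe
#' @return List with `strand`, `mfe`, `structure` and `sequence` (the RNA
#'   sequence that was folded).
#' @export
select_fold_strand <- function(cluster, genome, local_span = 150L,
                               backend = c("builtin", "vienna")) {
  backend <- match.arg(backend)
  stopifnot(length(cluster) == 1)
  sc <- as.character(GenomicRanges::seqnames(cluster))
  if (!sc %in% names(genome)) {
    stop_srna("scaffold '%s' absent from genome", sc)
  }
  dna <- as.character(Biostrings::subseq(
    genome[[sc]], GenomicRanges::start(cluster), GenomicRanges::end(cluster)))
  plus <- dna_to_rna(dna)
  strands <- S4Vectors::mcols(cluster)$strands
  if (is.null(strands) || is.na(strands) || strands %in% c("", "*")) {
    strands <- "+-"
  }
  if (strands == "+") {
    f <- fold_mfe(plus, local_span, backend)
    return(list(strand = "+", mfe = f$mfe, structure = f$structure,
                sequence = plus))
  }
  minus <- revcomp_rna(plus)
  if (strands == "-") {
    f <- fold_mfe(minus, local_span, backend)
    return(list(strand = "-", mfe = f$mfe, structure = f$structure,
                sequence = minus))
  }
  fp <- fold_mfe(plus, local_span, backend)
  fm <- fold_mfe(minus, local_span, backend)
  if (fm$mfe < fp$mfe) {
    list(strand = "-", mfe = fm$mfe, structure = fm$structure,
         sequence = minus)
  } else {
    list(strand = "+", mfe = fp$mfe, structure = fp$structure,
         sequence = plus)
  }
}

#' Dinucleotide-preserving shuffle
#'
#' Altschul-Erickson Eulerian-walk shuffle: the output is a random sequence
#' with exactly the same mononucleotide and dinucleotide counts as the input
#' (so base-stacking statistics are preserved in the folding null).
#' Deterministic for a given `rng_seed`.
#'
#' @param sequence Sequence of length >= 2.
#' @param rng_seed Optional integer seed; the caller's RNG state is left
#'   untouched.
#' @return The shuffled sequence (uppercase RNA alphabet).
#' @export
dinucleotide_shuffle <- function(sequence, rng_seed = NULL) {
  s <- normalize_rna(sequence)
  n <- nchar(s)
  if (n < 2) stop_srna("dinucleotide shuffle needs length >= 2")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (length(unique(chars)) == 1L || n == 2L) return(s)
  with_rng(rng_seed, paste(ae_shuffle(chars), collapse = ""))
}

# Altschul-Erickson: pick random designated last-exit edges forming an
# arborescence into the terminal vertex, randomise the remaining edge order,
# then walk the Eulerian path.
ae_shuffle <- function(chars) {
  n <- length(chars)
  src <- chars[-n]
  dst <- chars[-1]
  verts <- unique(chars)
  out <- split(dst, factor(src, levels = verts))
  last <- chars[n]
  sources <- verts[vapply(out, length, integer(1)) > 0]
  nonlast <- setdiff(sources, last)

  reaches_last <- function(le) {
    all(vapply(nonlast, function(v) {
      seen <- character(0)
      cur <- v
      repeat {
        if (cur == last) return(TRUE)
        if (cur %in% seen || !cur %in% nonlast) return(cur == last)
        seen <- c(seen, cur)
        cur <- le[[cur]]
      }
    }, logical(1)))
  }
  if (length(nonlast) > 0) {
    repeat {
      le <- vapply(nonlast, function(v) {
        e <- out[[v]]
        e[sample.int(length(e), 1L)]
      }, character(1))
      names(le) <- nonlast
      if (reaches_last(le)) break
    }
  }
  for (v in sources) {
    e <- out[[v]]
    if (v %in% nonlast) {
      i <- match(le[[v]], e)
      rest <- e[-i]
      if (length(rest) > 1) rest <- rest[sample.int(length(rest))]
      out[[v]] <- c(rest, le[[v]])
    } else if (length(e) > 1) {
      out[[v]] <- e[sample.int(length(e))]
    }
  }
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  res <- character(n)
  res[1] <- chars[1]
  cur <- chars[1]
  for (i in 2:n) {
    nxt <- out[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    res[i] <- nxt
    cur <- nxt
  }
  res
}

#' Shuffle-based significance of precursor structure
#'
#' Compares the minimum free energy of the native sequence against
#' `n_shuffles` dinucleotide-preserving shuffles of itself, with both native
#' and shuffled sequences folded by the same engine. The empirical p-value
#' uses the add-one convention, `p = (1 + #\{MFE_shuffle <= MFE_native\}) /
#' (n_shuffles + 1)`, bounded in `[1/(n+1), 1]`: it estimates the probability
#' that a composition-matched random sequence folds at least as stably as the
#' native one, i.e. how unlikely the observed structure is by chance.
#'
#' @inheritParams fold_mfe
#' @param n_shuffles Number of randomisations (default 100).
#' @param rng_seed Optional seed for the shuffles.
#' @return List with `p`, `native_mfe` and `n_shuffles`.
#' @export
randfold_test <- function(sequence, n_shuffles = 100L, rng_seed = NULL,
                          local_span = 150L,
                          backend = c("builtin", "vienna")) {
  backend <- match.arg(backend)
  if (n_shuffles < 1) stop_srna("n_shuffles must be >= 1")
  native <- fold_mfe(sequence, local_span, backend)$mfe
  k <- with_rng(rng_seed, {
    hits <- 0L
    for (i in seq_len(n_shuffles)) {
      sh <- dinucleotide_shuffle(sequence)
      if (fold_mfe(sh, local_span, backend)$mfe <= native + 1e-9) {
        hits <- hits + 1L
      }
    }
    hits
  })
  list(p = (1 + k) / (n_shuffles + 1), native_mfe = native,
       n_shuffles = as.integer(n_shuffles))
}

#' Fold and test every cluster
#'
#' Runs [select_fold_strand()] and [randfold_test()] over a cluster set,
#' attaching `fold_strand`, `mfe` and `randfold_p` metadata columns. Each
#' cluster gets a distinct, reproducible shuffle stream derived from
#' `rng_seed`.
#'
#' @param clusters Clusters (`GRanges`).
#' @param genome A `DNAStringSet`.
#' @inheritParams randfold_test
#' @return `clusters` with fold columns filled in.
#' @export
fold_clusters <- function(clusters, genome, n_shuffles = 100L,
                          rng_seed = NULL, local_span = 150L,
                          backend = c("builtin", "vienna")) {
  backend <- match.arg(backend)
  n <- length(clusters)
  strand_v <- character(n)
  mfe_v <- numeric(n)
  p_v <- numeric(n)
  for (i in seq_len(n)) {
    sf <- select_fold_strand(clusters[i], genome, local_span, backend)
    rf <- randfold_test(sf$sequence, n_shuffles,
                        rng_seed = if (is.null(rng_seed)) NULL
                                   else rng_seed + i,
                        local_span = local_span, backend = backend)
    strand_v[i] <- sf$strand
    mfe_v[i] <- sf$mfe
    p_v[i] <- rf$p
  }
  S4Vectors::mcols(clusters)$fold_strand <- strand_v
  S4Vectors::mcols(clusters)$mfe <- mfe_v
  S4Vectors::mcols(clusters)$randfold_p <- p_v
  clusters
}

#' Cumulative structure-significance curves per class
#'
#' For each focal cluster class and for the background (all clusters not in
#' any focal class), the percentage of clusters whose shuffle-test p-value is
#' at or below each cutoff. A structured class rises above the background at
#' stringent cutoffs; an unstructured one tracks it.
#'
#' @param clusters Classified clusters carrying `randfold_p`.
#' @param focal_classes Classes compared against the background.
#' @param cutoffs P-value cutoffs (default 0.01, 0.02, 0.05, 0.1).
#' @return `data.frame` with columns `class`, `cutoff`, `percent`, `n`.
#' @export
structure_enrichment_curves <- function(clusters,
                                        focal_classes = c("endo_siRNA",
                                                          "piRNA"),
                                        cutoffs = c(0.01, 0.02, 0.05, 0.1)) {
  p <- S4Vectors::mcols(clusters)$randfold_p
  if (is.null(p) || anyNA(p)) {
    stop_srna("run fold_clusters() before structure_enrichment_curves()")
  }
  lab <- as.character(S4Vectors::mcols(clusters)$class)
  groups <- c(as.list(intersect(focal_classes, unique(lab))),
              list(background = setdiff(unique(lab), focal_classes)))
  names(groups)[seq_along(intersect(focal_classes, unique(lab)))] <-
    intersect(focal_classes, unique(lab))
  rows <- lapply(names(groups), function(g) {
    sel <- lab %in% groups[[g]]
    data.frame(class = g, cutoff = cutoffs,
               percent = vapply(cutoffs, function(ct) {
                 if (sum(sel) == 0) return(NA_real_)
                 100 * mean(p[sel] <= ct)
               }, numeric(1)),
               n = sum(sel), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
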