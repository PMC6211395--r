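#' Specification for a synthetic small-RNA study
#'
#' Defines the study conditions for the toy genome and libraries: scaffold
#' sizes, how many loci of each class are planted, the per-class read-length
#' and diversity models, the sequence biases enforced at piRNA/25-mer loci,
#' and how multi-mapping is created (literal duplication of a transposon
#' family sequence, so mapping multiplicity is exactly computable by
#' occurrence counting, without an aligner).
#'
#' Class models mirror the biology being emulated: miRNA-like loci are
#' hairpin cassettes emitting one dominant mature read plus a few
#' low-abundance variants and a star read (few distinct reads, high
#' uniformity); endo-siRNA-like loci are longer inverted repeats emitting
#' many distinct 20-22 nt reads of low individual abundance; piRNA-like loci
#' are unstructured regions emitting diverse 26-28 nt reads with enforced
#' 5' U and position-10 A frequencies and an optional downstream-G tail
#' bias; 25-mer loci emit 24-26 nt reads with a 5' U bias only.
#'
#' @param scaffold_lengths Named integer vector of scaffold lengths.
#' @param n_mirna,n_endo,n_pirna,n_mer25 Planted locus counts per class.
#' @param mirna_depth Expected abundance of the dominant mature read.
#' @param endo_reads,pirna_reads,mer25_reads Distinct reads planted per
#'   locus.
#' @param endo_count_mean Mean abundance per distinct endo-siRNA read.
#' @param pirna_u1,pirna_a10 Enforced position-1 U and position-10 A
#'   frequencies at piRNA loci.
#' @param pirna_downstream_g Per-position probability of a G in read
#'   positions beyond 25 at piRNA loci (0 disables the tail bias).
#' @param mer25_u1 Enforced 5' U frequency at 25-mer loci.
#' @param endo_len_weights,pirna_len_weights,mer25_len_weights Named
#'   read-length sampling weights per class.
#' @param transposon_copies Copies per transposon family (multimapper copy
#'   number).
#' @param transposon_len Transposon family length in bp.
#' @param frac_pirna_transposon Fraction of piRNA loci placed inside
#'   transposon families.
#' @param n_genes Standalone (non-cis-NAT) coding gene models.
#' @param frac_endo_cis_nat Fraction of endo-siRNA loci embedded in a
#'   cis-NAT gene pair.
#' @param n_rrna rRNA loci planted (their reads must be removed upstream).
#' @param rrna_reads Distinct reads per rRNA locus.
#' @return A validated list of class `sim_spec`.
#' @export
sim_spec <- function(scaffold_lengths = c(sc1 = 60000L, sc2 = 60000L,
                                          sc3 = 60000L),
                     n_mirna = 8L, n_endo = 12L, n_pirna = 12L,
                     n_mer25 = 6L,
                     mirna_depth = 120, endo_reads = 30L,
                     endo_count_mean = 1.3,
                     pirna_reads = 40L, pirna_u1 = 0.8, pirna_a10 = 0.6,
                     pirna_downstream_g = 0.5,
                     mer25_reads = 30L, mer25_u1 = 0.8,
                     endo_len_weights = c("20" = 0.2, "21" = 0.6,
                                          "22" = 0.2),
                     pirna_len_weights = c("26" = 0.25, "27" = 0.5,
                                           "28" = 0.25),
                     mer25_len_weights = c("24" = 0.25, "25" = 0.5,
                                           "26" = 0.25),
                     transposon_copies = 3L, transposon_len = 600L,
                     frac_pirna_transposon = 0.5,
                     n_genes = 24L, frac_endo_cis_nat = 0.5,
                     n_rrna = 2L, rrna_reads = 5L) {
  freqs <- c(pirna_u1, pirna_a10, pirna_downstream_g, mer25_u1,
             frac_pirna_transposon, frac_endo_cis_nat)
  if (any(freqs < 0 | freqs > 1)) {
    stop_srna("all frequencies must lie in [0, 1]")
  }
  if (is.null(names(scaffold_lengths))) {
    names(scaffold_lengths) <- sprintf("sc%d", seq_along(scaffold_lengths))
  }
  spec <- list(scaffold_lengths = as.integer(scaffold_lengths),
               n_mirna = n_mirna, n_endo = n_endo, n_pirna = n_pirna,
               n_mer25 = n_mer25, mirna_depth = mirna_depth,
               endo_reads = endo_reads, endo_count_mean = endo_count_mean,
               pirna_reads = pirna_reads, pirna_u1 = pirna_u1,
               pirna_a10 = pirna_a10,
               pirna_downstream_g = pirna_downstream_g,
               mer25_reads = mer25_reads, mer25_u1 = mer25_u1,
               endo_len_weights = endo_len_weights,
               pirna_len_weights = pirna_len_weights,
               mer25_len_weights = mer25_len_weights,
               transposon_copies = as.integer(transposon_copies),
               transposon_len = as.integer(transposon_len),
               frac_pirna_transposon = frac_pirna_transposon,
               n_genes = n_genes, frac_endo_cis_nat = frac_endo_cis_nat,
               n_rrna = n_rrna, rrna_reads = rrna_reads)
  names(spec$scaffold_lengths) <- names(scaffold_lengths)
  class(spec) <- "sim_spec"
  spec
}

SIM_MARGIN <- 300L
SIM_PITCH <- 1300L
SIM_SLOT <- 600L

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_dna <- function(x) {
  vapply(x, function(s) {
    rc <- chartr("ACGT", "TGCA", s)
    paste(rev(strsplit(rc, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

put_dna <- function(scaffolds, sc, at0, frag) {
  substr(scaffolds[[sc]], at0 + 1L, at0 + nchar(frag)) <- frag
  scaffolds
}

sample_lengths <- function(n, weights) {
  lens <- as.integer(names(weights))
  lens[sample.int(length(lens), n, replace = TRUE, prob = weights)]
}

#' Simulate a toy genome with planted small-RNA loci
#'
#' Builds random scaffolds and plants, per [sim_spec()]: miRNA hairpin
#' cassettes (recorded in a known-miRNA track), endo-siRNA inverted repeats
#' (half of them embedded in overlapping antisense gene pairs, the cis-NAT
#' configuration), unique piRNA loci, transposon-resident piRNA loci (the
#' family sequence is pasted at several positions so its reads become
#' multimappers), 25-mer loci, rRNA loci and standalone gene models with
#' exon/intron/UTR structure. Sequence biases (5' U, position-10 A,
#' downstream G) are written into the genome at the pre-drawn read template
#' positions, so extracted reads carry the biases while still matching the
#' genome exactly.
#'
#' @param spec A [sim_spec()].
#' @param rng_seed Integer seed; the same seed reproduces the genome
#'   byte-for-byte.
#' @return A list of class `srna_sim`: `genome` (`DNAStringSet`),
#'   `scaffold_lengths`, `tracks` (named list of annotation `GRanges`),
#'   `truth` (planted locus table with class and coordinates) and
#'   `templates` (pre-drawn read layout used by [simulate_library()]).
#' @export
simulate_genome <- function(spec, rng_seed = 1L) {
  stopifnot(inherits(spec, "sim_spec"))
  with_rng(rng_seed, simulate_genome_impl(spec))
}

simulate_genome_impl <- function(spec) {
  sl <- spec$scaffold_lengths
  scaffolds <- lapply(sl, rand_dna)

  # fixed slot grid; loci are shuffled over slots
  slot_tab <- do.call(rbind, lapply(names(sl), function(sc) {
    n_slot <- max(0L, (sl[[sc]] - 2L * SIM_MARGIN) %/% SIM_PITCH)
    if (n_slot == 0) return(NULL)
    data.frame(scaffold = sc,
               start0 = SIM_MARGIN + (seq_len(n_slot) - 1L) * SIM_PITCH,
               stringsAsFactors = FALSE)
  }))
  n_tp <- round(spec$frac_pirna_transposon * spec$n_pirna)
  n_pirna_u <- spec$n_pirna - n_tp
  n_cis <- round(spec$frac_endo_cis_nat * spec$n_endo)
  needed <- spec$n_mirna + spec$n_endo + n_pirna_u +
    n_tp * spec$transposon_copies + spec$n_mer25 + spec$n_rrna + spec$n_genes
  if (is.null(slot_tab) || needed > nrow(slot_tab)) {
    stop_srna("spec infeasible: %d loci requested but only %d slots fit",
              needed, if (is.null(slot_tab)) 0L else nrow(slot_tab))
  }
  slot_tab <- slot_tab[sample.int(nrow(slot_tab)), , drop = FALSE]
  cursor <- 0L
  take_slot <- function() {
    cursor <<- cursor + 1L
    slot_tab[cursor, ]
  }

  truth <- list()
  templates <- list()
  tracks <- list(
    known_miRNA = list(), rRNA = list(), transposon_known = list(),
    gene_model = list(), exon = list(), intron = list(),
    utr5 = list(), utr3 = list()
  )
  add <- function(store, sc, s0, e0, strand, name) {
    store[[length(store) + 1L]] <- data.frame(
      scaffold = sc, start0 = s0, end0 = e0, strand = strand, name = name,
      stringsAsFactors = FALSE)
    store
  }
  add_truth <- function(id, class, sc, s0, e0, strand, multi = FALSE) {
    truth[[length(truth) + 1L]] <<- data.frame(
      locus_id = id, class = class, scaffold = sc, start0 = s0, end0 = e0,
      strand = strand, multi = multi, stringsAsFactors = FALSE)
  }
  add_template <- function(id, sc, s0, len, strand, role) {
    templates[[length(templates) + 1L]] <<- data.frame(
      locus_id = id, scaffold = sc, start0 = s0, end0 = s0 + len,
      strand = strand, role = role, stringsAsFactors = FALSE)
  }

  # --- miRNA hairpins: dominant mature + shifted variants + star ----------
  for (i in seq_len(spec$n_mirna)) {
    slot <- take_slot()
    id <- sprintf("mir%02d", i)
    arm <- rand_dna(30L)
    cassette <- paste0(arm, rand_dna(10L), revcomp_dna(arm))
    scaffolds <- put_dna(scaffolds, slot$scaffold, slot$start0, cassette)
    s0 <- slot$start0
    add_truth(id, "mirna", slot$scaffold, s0, s0 + 70L, "+")
    tracks$known_miRNA <- add(tracks$known_miRNA, slot$scaffold, s0,
                              s0 + 70L, "+", id)
    add_template(id, slot$scaffold, s0 + 4L, 22L, "+", "mature")
    add_template(id, slot$scaffold, s0 + 5L, 22L, "+", "variant")
    add_template(id, slot$scaffold, s0 + 4L, 21L, "+", "variant")
    add_template(id, slot$scaffold, s0 + 44L, 22L, "-", "star")
  }

  # --- endo-siRNA inverted repeats (some inside cis-NAT gene pairs) -------
  for (i in seq_len(spec$n_endo)) {
    slot <- take_slot()
    id <- sprintf("endo%02d", i)
    stem <- rand_dna(80L)
    cassette <- paste0(stem, rand_dna(10L), revcomp_dna(stem))
    span <- nchar(cassette)
    scaffolds <- put_dna(scaffolds, slot$scaffold, slot$start0, cassette)
    s0 <- slot$start0
    add_truth(id, "endo", slot$scaffold, s0, s0 + span, "+")
    lens <- sample_lengths(spec$endo_reads, spec$endo_len_weights)
    offs <- sample.int(span - max(lens), spec$endo_reads, replace = TRUE) - 1L
    strands <- sample(c("+", "-"), spec$endo_reads, replace = TRUE)
    keep <- !duplicated(paste(offs, lens, strands))
    for (k in which(keep)) {
      add_template(id, slot$scaffold, s0 + offs[k], lens[k], strands[k],
                   "endo")
    }
    if (i <= n_cis) {
      gp <- sprintf("%s_gp", id)
      gm <- sprintf("%s_gm", id)
      e0 <- s0 + span
      tracks$gene_model <- add(tracks$gene_model, slot$scaffold, s0 - 200L,
                               e0 + 50L, "+", gp)
      tracks$gene_model <- add(tracks$gene_model, slot$scaffold, s0 - 50L,
                               e0 + 200L, "-", gm)
      tracks$utr5 <- add(tracks$utr5, slot$scaffold, s0 - 200L, s0 - 150L,
                         "+", gp)
      tracks$utr3 <- add(tracks$utr3, slot$scaffold, e0, e0 + 50L, "+", gp)
      tracks$exon <- add(tracks$exon, slot$scaffold, s0 - 150L, e0, "+", gp)
      tracks$utr5 <- add(tracks$utr5, slot$scaffold, e0 + 150L, e0 + 200L,
                         "-", gm)
      tracks$utr3 <- add(tracks$utr3, slot$scaffold, s0 - 50L, s0, "-", gm)
      tracks$exon <- add(tracks$exon, slot$scaffold, s0, e0 + 150L, "-", gm)
    }
  }

  # --- piRNA loci: biased-read layout written into the genome -------------
  plant_biased_reads <- function(seqstr, n_reads, len_weights, u1, a10,
                                 dg, locus_strand) {
    span <- nchar(seqstr)
    lens <- sample_lengths(n_reads, len_weights)
    offs <- sample.int(span - max(lens), n_reads, replace = TRUE) - 1L
    keep <- !duplicated(paste(offs, lens))
    lens <- lens[keep]
    offs <- offs[keep]
    ch <- strsplit(seqstr, "", fixed = TRUE)[[1]]
    # read position p (1-based, 5'-anchored) sits at locus offset
    # off + p - 1 on a plus locus, and at off + len - p on a minus locus,
    # where the template base is the complement of the read base
    poke <- function(off, len, p, read_base) {
      if (p > len) return()
      if (locus_strand == "+") {
        ch[off + p] <<- read_base
      } else {
        ch[off + len - p + 1L] <<- chartr("ACGT", "TGCA", read_base)
      }
    }
    for (k in seq_along(offs)) {
      if (stats::runif(1) < u1) poke(offs[k], lens[k], 1L, "T")
      if (a10 > 0 && stats::runif(1) < a10) poke(offs[k], lens[k], 10L, "A")
      if (dg > 0 && lens[k] > 25L) {
        for (p in 26:lens[k]) {
          if (stats::runif(1) < dg) poke(offs[k], lens[k], p, "G")
        }
      }
    }
    list(seq = paste(ch, collapse = ""), offs = offs, lens = lens)
  }

  for (i in seq_len(spec$n_pirna)) {
    id <- sprintf("pir%02d", i)
    strand <- sample(c("+", "-"), 1L)
    in_tp <- i <= n_tp
    span <- if (in_tp) spec$transposon_len else 300L
    pl <- plant_biased_reads(rand_dna(span), spec$pirna_reads,
                             spec$pirna_len_weights, spec$pirna_u1,
                             spec$pirna_a10, spec$pirna_downstream_g,
                             strand)
    n_copies <- if (in_tp) spec$transposon_copies else 1L
    for (cp in seq_len(n_copies)) {
      slot <- take_slot()
      scaffolds <- put_dna(scaffolds, slot$scaffold, slot$start0, pl$seq)
      s0 <- slot$start0
      add_truth(if (cp == 1) id else sprintf("%s_cp%d", id, cp), "pirna",
                slot$scaffold, s0, s0 + span, strand, multi = in_tp)
      if (in_tp) {
        tracks$transposon_known <- add(tracks$transposon_known,
                                       slot$scaffold, s0, s0 + span, "+",
                                       sprintf("tp_%s_cp%d", id, cp))
      }
      if (cp == 1) {
        for (k in seq_along(pl$offs)) {
          add_template(id, slot$scaffold, s0 + pl$offs[k], pl$lens[k],
                       strand, "pirna")
        }
      }
    }
  }

  # --- 25-mer loci: 5' U bias only ----------------------------------------
  for (i in seq_len(spec$n_mer25)) {
    slot <- take_slot()
    id <- sprintf("m25_%02d", i)
    strand <- sample(c("+", "-"), 1L)
    pl <- plant_biased_reads(rand_dna(200L), spec$mer25_reads,
                             spec$mer25_len_weights, spec$mer25_u1,
                             0, 0, strand)
    scaffolds <- put_dna(scaffolds, slot$scaffold, slot$start0, pl$seq)
    s0 <- slot$start0
    add_truth(id, "mer25", slot$scaffold, s0, s0 + 200L, strand)
    for (k in seq_along(pl$offs)) {
      add_template(id, slot$scaffold, s0 + pl$offs[k], pl$lens[k], strand,
                   "mer25")
    }
  }

  # --- rRNA loci (reads to be excluded upstream) --------------------------
  for (i in seq_len(spec$n_rrna)) {
    slot <- take_slot()
    id <- sprintf("rrna%02d", i)
    s0 <- slot$start0
    add_truth(id, "rrna", slot$scaffold, s0, s0 + 200L, "+")
    tracks$rRNA <- add(tracks$rRNA, slot$scaffold, s0, s0 + 200L, "+", id)
    lens <- sample(18:24, spec$rrna_reads, replace = TRUE)
    offs <- sample.int(200L - 24L, spec$rrna_reads, replace = TRUE) - 1L
    keep <- !duplicated(paste(offs, lens))
    for (k in which(keep)) {
      add_template(id, slot$scaffold, s0 + offs[k], lens[k], "+", "rrna")
    }
  }

  # --- standalone gene models with exon/intron/UTR structure --------------
  for (i in seq_len(spec$n_genes)) {
    slot <- take_slot()
    gid <- sprintf("gene%02d", i)
    strand <- if (i %% 2 == 0) "-" else "+"
    s0 <- slot$start0
    e0 <- s0 + 400L
    tracks$gene_model <- add(tracks$gene_model, slot$scaffold, s0, e0,
                             strand, gid)
    if (strand == "+") {
      tracks$utr5 <- add(tracks$utr5, slot$scaffold, s0, s0 + 50L, "+", gid)
      tracks$utr3 <- add(tracks$utr3, slot$scaffold, e0 - 50L, e0, "+", gid)
    } else {
      tracks$utr5 <- add(tracks$utr5, slot$scaffold, e0 - 50L, e0, "-", gid)
      tracks$utr3 <- add(tracks$utr3, slot$scaffold, s0, s0 + 50L, "-", gid)
    }
    tracks$exon <- add(tracks$exon, slot$scaffold, s0 + 50L, s0 + 150L,
                       strand, gid)
    tracks$intron <- add(tracks$intron, slot$scaffold, s0 + 150L, s0 + 250L,
                         strand, gid)
    tracks$exon <- add(tracks$exon, slot$scaffold, s0 + 250L, s0 + 350L,
                       strand, gid)
  }

  track_gr <- lapply(names(tracks), function(cls) {
    rows <- tracks[[cls]]
    if (length(rows) == 0) {
      gr <- GenomicRanges::GRanges()
      S4Vectors::mcols(gr)$name <- character(0)
    } else {
      df <- do.call(rbind, rows)
      gr <- annotation_track(df$scaffold, df$start0, df$end0, df$strand,
                             element_class = cls, name = df$name)
    }
    S4Vectors::metadata(gr)$element_class <- cls
    gr
  })
  names(track_gr) <- names(tracks)

  genome <- Biostrings::DNAStringSet(unlist(scaffolds))
  names(genome) <- names(sl)
  structure(list(genome = genome,
                 scaffold_lengths = stats::setNames(as.numeric(sl),
                                                    names(sl)),
                 tracks = track_gr,
                 truth = do.call(rbind, truth),
                 templates = do.call(rbind, templates),
                 spec = spec),
            class = "srna_sim")
}

#' Simulate a mapped small-RNA library from a synthetic genome
#'
#' Draws abundances for the pre-planted read templates, extracts their
#' sequences from the genome, and emits one mapping record per exact genomic
#' occurrence of each distinct sequence (both strands searched), with
#' `n_mappings` equal to the total occurrence count -- transposon-family
#' reads therefore come out as multimappers with one record per copy.
#'
#' @param sim Output of [simulate_genome()].
#' @param rng_seed Integer seed for the abundance draws.
#' @param expressed_loci Optional character vector of locus ids to express
#'   (default: all); use different subsets to emulate developmental stages.
#' @param depth_scale Multiplies all expected abundances (default 1); use
#'   values above 1 to emulate deeper sequencing of the same loci.
#' @return Mapped reads (`GRanges` as from [read_mapped_reads()]).
#' @export
simulate_library <- function(sim, rng_seed = NULL, expressed_loci = NULL,
                             depth_scale = 1) {
  stopifnot(inherits(sim, "srna_sim"))
  tpl <- sim$templates
  if (!is.null(expressed_loci)) {
    tpl <- tpl[tpl$locus_id %in% expressed_loci, , drop = FALSE]
  }
  if (nrow(tpl) == 0) return(empty_mapped_reads())
  spec <- sim$spec

  with_rng(rng_seed, {
    lambda <- c(
      mature = spec$mirna_depth * 0.8, variant = 1, star = 2,
      endo = max(spec$endo_count_mean - 1, 0), pirna = 0.3, mer25 = 0.3,
      rrna = 0.5
    ) * depth_scale
    base <- c(mature = 5L, variant = 1L, star = 1L, endo = 1L, pirna = 1L,
              mer25 = 1L, rrna = 1L)
    counts <- base[tpl$role] +
      stats::rpois(nrow(tpl), lambda[tpl$role])

    seqs <- character(nrow(tpl))
    for (i in seq_len(nrow(tpl))) {
      frag <- as.character(Biostrings::subseq(
        sim$genome[[tpl$scaffold[i]]], tpl$start0[i] + 1L, tpl$end0[i]))
      if (tpl$strand[i] == "-") frag <- revcomp_dna(frag)
      seqs[i] <- dna_to_rna(frag)
    }
    agg <- tapply(counts, seqs, sum)
    distinct <- names(agg)
    occ <- locate_occurrences(distinct, sim$genome)
    n_map <- stats::setNames(
      vapply(occ, function(o) sum(vapply(o, nrow, integer(1))), integer(1)),
      distinct)

    rows <- list()
    for (s in distinct) {
      for (sc in names(occ[[s]])) {
        hits <- occ[[s]][[sc]]
        if (nrow(hits) == 0) next
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold = sc, start0 = hits$start0, end0 = hits$end0,
          strand = hits$strand, sequence = s,
          count = as.integer(agg[[s]]), n_mappings = n_map[[s]],
          stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    mapped_reads(df$scaffold, df$start0, df$end0, df$strand, df$sequence,
                 df$count, df$n_mappings, source = "simulate_library")
  })
}

# Exact occurrence search of RNA read sequences against a DNA genome, both
# strands, grouped by read width so constant-width dictionaries apply.
locate_occurrences <- function(sequences, genome) {
  dna <- rna_to_dna(sequences)
  out <- lapply(sequences, function(s) {
    stats::setNames(
      rep(list(data.frame(start0 = integer(0), end0 = integer(0),
                          strand = character(0))), length(genome)),
      names(genome))
  })
  names(out) <- sequences
  widths <- nchar(dna)
  for (w in unique(widths)) {
    idx <- which(widths == w)
    fwd <- Biostrings::DNAStringSet(dna[idx])
    rev <- Biostrings::reverseComplement(fwd)
    pd_f <- Biostrings::PDict(fwd)
    pd_r <- Biostrings::PDict(rev)
    for (sc in names(genome)) {
      subject <- genome[[sc]]
      hits_f <- Biostrings::matchPDict(pd_f, subject)
      hits_r <- Biostrings::matchPDict(pd_r, subject)
      for (k in seq_along(idx)) {
        s <- sequences[idx[k]]
        hf <- hits_f[[k]]
        hr <- hits_r[[k]]
        df <- rbind(
          if (length(hf) > 0) data.frame(start0 = IRanges::start(hf) - 1L,
                                         end0 = IRanges::end(hf),
                                         strand = "+") else NULL,
          if (length(hr) > 0) data.frame(start0 = IRanges::start(hr) - 1L,
                                         end0 = IRanges::end(hr),
                                         strand = "-") else NULL)
        if (!is.null(df) && nrow(df) > 0) out[[s]][[sc]] <- df
      }
    }
  }
  out
}

#' Recovery of planted loci by the classification pipeline
#'
#' Matches classified clusters against the simulator's ground truth: a
#' planted locus is recovered when at least one cluster overlapping it by at
#' least one nucleotide carries the expected label (miRNA-like loci are
#' expected as `known_miRNA`, endo-siRNA as `endo_siRNA`, piRNA as `piRNA`,
#' 25-mer as `mer25`). rRNA loci are excluded (their reads are removed
#' before clustering).
#'
#' @param classified Classified clusters (`GRanges` with `class`).
#' @param truth Truth table from [simulate_genome()].
#' @return `data.frame` per class: `n_loci`, `n_recovered`, `recall`; an
#'   `overall` row aggregates all classes.
#' @export
evaluate_recovery <- function(classified, truth) {
  expected <- c(mirna = "known_miRNA", endo = "endo_siRNA",
                pirna = "piRNA", mer25 = "mer25")
  truth <- truth[truth$class %in% names(expected), , drop = FALSE]
  tr_gr <- gr_from_bed0(truth$scaffold, truth$start0, truth$end0)
  lab <- as.character(S4Vectors::mcols(classified)$class)
  ov <- GenomicRanges::findOverlaps(tr_gr, classified, ignore.strand = TRUE)
  hit_lab <- split(lab[S4Vectors::subjectHits(ov)],
                   S4Vectors::queryHits(ov))
  recovered <- vapply(seq_len(nrow(truth)), function(i) {
    labs <- hit_lab[[as.character(i)]]
    !is.null(labs) && expected[[truth$class[i]]] %in% labs
  }, logical(1))
  per <- lapply(names(expected), function(cls) {
    sel <- truth$class == cls
    data.frame(class = cls, n_loci = sum(sel),
               n_recovered = sum(recovered[sel]),
               recall = if (sum(sel) == 0) NA_real_
                        else mean(recovered[sel]),
               stringsAsFactors = FALSE)
  })
  rbind(do.call(rbind, per),
        data.frame(class = "overall", n_loci = nrow(truth),
                   n_recovered = sum(recovered),
                   recall = mean(recovered), stringsAsFactors = FALSE))
}
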