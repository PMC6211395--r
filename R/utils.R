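# shared internal helpers

ELEMENT_CLASSES <- c("exon", "intron", "utr5", "utr3",
                     "transposon_known", "transposon_unknown",
                     "rRNA", "tRNA", "snoRNA", "known_miRNA", "gene_model")

CLASS_LABELS <- c("known_miRNA", "miRNA_candidate_HU", "tRNA", "snoRNA",
                  "endo_siRNA", "piRNA", "mer25", "unclassified")

# Evaluate `expr` under a temporary RNG state when `seed` is given, restoring
# the caller's stream afterwards so seeded helpers do not perturb a session.
with_rng <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# T and U are equivalent on input; sequences are stored uppercase with U.
normalize_rna <- function(x) {
  chartr("tT u", "UU U", toupper(x))
}

rna_to_dna <- function(x) chartr("U", "T", toupper(x))
dna_to_rna <- function(x) chartr("T", "U", toupper(x))

revcomp_rna <- function(x) {
  vapply(x, function(s) {
    rc <- chartr("ACGU", "UGCA", s)
    paste(rev(strsplit(rc, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

stop_srna <- function(...) stop(sprintf(...), call. = FALSE)

# 0-based half-open file coordinates <-> 1-based closed GRanges
gr_from_bed0 <- function(scaffold, start0, end0, strand = "*") {
  n <- length(start0)
  GenomicRanges::GRanges(
    seqnames = rep_len(scaffold, n),
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = rep_len(strand, n)
  )
}

bed0_start <- function(gr) GenomicRanges::start(gr) - 1L
bed0_end <- function(gr) GenomicRanges::end(gr)

# fixed-format numeric rendering for reproducible report files
fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}
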