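# shared fixture builders; everything is generated in code

rand_seq <- function(len) {
  vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "U"), l, replace = TRUE), collapse = "")
  }, character(1))
}

mk_reads <- function(scaffold, start, len, strand = "+", count = 1L,
                     nmap = 1L, seq = NULL) {
  n <- length(start)
  scaffold <- rep_len(scaffold, n)
  strand <- rep_len(strand, n)
  count <- rep_len(as.integer(count), n)
  nmap <- rep_len(as.integer(nmap), n)
  len <- rep_len(as.integer(len), n)
  if (is.null(seq)) seq <- rand_seq(len)
  mapped_reads(scaffold, start, start + len, strand, seq, count, nmap)
}

rc_rna <- function(x) {
  y <- chartr("ACGU", "UGCA", x)
  vapply(y, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

# a random-arm hairpin folds strongly but its dinucleotide shuffles do not
mk_hairpin <- function(arm_len = 30, loop = "AACAAG") {
  arm <- rand_seq(arm_len)
  paste0(arm, loop, rc_rna(arm))
}

small_spec <- function() {
  sim_spec(scaffold_lengths = c(sc1 = 20000L, sc2 = 20000L),
           n_mirna = 3L, n_endo = 4L, n_pirna = 4L, n_mer25 = 2L,
           n_genes = 6L, n_rrna = 2L)
}

# cache the shared small simulation across test files
shared_sim <- local({
  sim <- NULL
  function() {
    if (is.null(sim)) sim <<- simulate_genome(small_spec(), rng_seed = 101L)
    sim
  }
})

shared_lib <- local({
  lib <- NULL
  function() {
    if (is.null(lib)) lib <<- simulate_library(shared_sim(), rng_seed = 102L)
    lib
  }
})

shared_classified <- local({
  cl <- NULL
  function() {
    if (!is.null(cl)) return(cl)
    sim <- shared_sim()
    filt <- filter_multimappers(shared_lib())
    rd <- exclude_rrna(filt$all_reads, sim$tracks$rRNA)
    x <- build_clusters(rd)
    cl <<- classify_clusters(x, sim$tracks, class_config("mnemiopsis"))
    cl
  }
})
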