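#' Positional nucleotide bias matrix
#'
#' Anchors every read at its 5' nucleotide and tabulates, for each position,
#' the percentage contribution of each base among the reads long enough to
#' cover that position. By default reads are weighted by their abundance
#' (`count`); set `weight_by_count = FALSE` to weight each distinct read
#' once. Positions covered by no read are reported as `NA`, not zero.
#'
#' @param reads Mapped reads (`GRanges` with `sequence`/`count` columns) or a
#'   character vector of sequences.
#' @param weight_by_count Weight reads by abundance (default `TRUE`).
#' @param counts Abundances when `reads` is a character vector; recycled to
#'   1 when omitted.
#' @return A numeric matrix (positions x `A,C,G,U`), percentages summing to
#'   100 at every covered position, with attribute `coverage` giving the
#'   summed weight of reads covering each position.
#' @export
positional_bias <- function(reads, weight_by_count = TRUE, counts = NULL) {
  if (inherits(reads, "GRanges")) {
    seqs <- S4Vectors::mcols(reads)$sequence
    counts <- S4Vectors::mcols(reads)$count
    # a multi-mapping sequence contributes once, not once per mapping
    first <- !duplicated(seqs)
    seqs <- seqs[first]
    counts <- counts[first]
  } else {
    seqs <- normalize_rna(reads)
    if (is.null(counts)) counts <- rep(1L, length(seqs))
  }
  if (length(seqs) == 0) stop_srna("positional_bias needs at least one read")
  w <- if (weight_by_count) as.numeric(counts) else rep(1, length(seqs))

  P <- max(nchar(seqs))
  bases <- c("A", "C", "G", "U")
  tab <- matrix(0, nrow = P, ncol = 4, dimnames = list(NULL, bases))
  cov <- numeric(P)
  mat <- matrix("", nrow = length(seqs), ncol = P)
  sp <- strsplit(seqs, "", fixed = TRUE)
  for (i in seq_along(sp)) mat[i, seq_along(sp[[i]])] <- sp[[i]]
  for (p in seq_len(P)) {
    col <- mat[, p]
    has <- col != ""
    cov[p] <- sum(w[has])
    if (cov[p] == 0) next
    for (b in bases) tab[p, b] <- sum(w[has & col == b])
  }
  pct <- tab / ifelse(cov > 0, cov, NA) * 100
  pct[cov == 0, ] <- NA_real_
  attr(pct, "coverage") <- cov
  class(pct) <- c("srna_bias", class(pct))
  pct
}

#' Detect the ping-pong biogenesis signature
#'
#' Secondary piRNA biogenesis leaves a joint bias for uridine at read
#' position 1 and adenosine at position 10. The signature is called positive
#' when U is the modal base at position 1 with at least `u1_min` percent and
#' A is the modal base at position 10 with at least `a10_min` percent.
#' Endo-siRNA populations typically show only the 5' U bias and are negative.
#'
#' @param bias A matrix from [positional_bias()] with at least 10 positions.
#' @param u1_min Minimum position-1 U percentage (default 40).
#' @param a10_min Minimum position-10 A percentage (default 35).
#' @return List: `positive` (logical), `u1` and `a10` (observed percentages).
#' @export
detect_ping_pong <- function(bias, u1_min = 40, a10_min = 35) {
  if (nrow(bias) < 10) stop_srna("bias matrix needs >= 10 positions")
  p1 <- bias[1, ]
  p10 <- bias[10, ]
  u1 <- unname(p1["U"])
  a10 <- unname(p10["A"])
  pos <- !anyNA(p1) && !anyNA(p10) &&
    names(which.max(p1)) == "U" && u1 >= u1_min &&
    names(which.max(p10)) == "A" && a10 >= a10_min
  list(positive = isTRUE(pos), u1 = u1, a10 = a10)
}

#' Detect 5' uridine bias
#'
#' The single-position counterpart of [detect_ping_pong()]: positive when U
#' is the modal base at position 1 at or above `u1_min` percent, the bias
#' common to endo-siRNA, piRNA and 25-mer populations.
#'
#' @inheritParams detect_ping_pong
#' @return List: `positive`, `u1`.
#' @export
detect_5prime_u <- function(bias, u1_min = 40) {
  p1 <- bias[1, ]
  u1 <- unname(p1["U"])
  pos <- !anyNA(p1) && names(which.max(p1)) == "U" && u1 >= u1_min
  list(positive = isTRUE(pos), u1 = u1)
}

#' Detect downstream guanosine enrichment
#'
#' G-quadruplex-like landmarks in piRNA precursors show up as a guanosine
#' enrichment downstream of position 25 in 5'-anchored bias profiles. The
#' call is positive when the mean G percentage over positions beyond
#' `from_position` exceeds `enrichment_factor` times the mean G percentage
#' over positions 2..`from_position` (position 1 is excluded because of the
#' 5' U bias). When no read extends beyond `from_position` the status is
#' `"indeterminate"`.
#'
#' @param bias A matrix from [positional_bias()].
#' @param from_position Boundary position (default 25).
#' @param enrichment_factor Required fold enrichment (default 1.25).
#' @return List: `status` (`"positive"`, `"negative"` or `"indeterminate"`),
#'   `mean_g_downstream`, `mean_g_upstream`, `ratio`.
#' @export
detect_downstream_g <- function(bias, from_position = 25,
                                enrichment_factor = 1.25) {
  P <- nrow(bias)
  down <- if (P > from_position) bias[(from_position + 1L):P, "G"] else NA
  down <- down[!is.na(down)]
  if (length(down) == 0) {
    return(list(status = "indeterminate", mean_g_downstream = NA_real_,
                mean_g_upstream = NA_real_, ratio = NA_real_))
  }
  up <- bias[2:min(from_position, P), "G"]
  up <- up[!is.na(up)]
  mu_d <- mean(down)
  mu_u <- mean(up)
  ratio <- mu_d / mu_u
  list(status = if (isTRUE(ratio > enrichment_factor)) "positive"
       else "negative",
       mean_g_downstream = mu_d, mean_g_upstream = mu_u, ratio = ratio)
}

#' Write a bias matrix as TSV
#'
#' Position rows, base columns, percentages to two decimals; uncovered
#' positions emit `NA`.
#'
#' @param bias Matrix from [positional_bias()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bias_matrix <- function(bias, path) {
  df <- data.frame(position = seq_len(nrow(bias)),
                   A = fmt_num(bias[, "A"], 4), C = fmt_num(bias[, "C"], 4),
                   G = fmt_num(bias[, "G"], 4), U = fmt_num(bias[, "U"], 4),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
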