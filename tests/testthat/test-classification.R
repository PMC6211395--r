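h <- function(...) {
  x <- c(...)
  stats::setNames(as.integer(x), names(x))
}

test_that("peak length is the count mode with ties toward the shorter", {
  expect_equal(peak_length(h("21" = 30, "22" = 10, "26" = 8)), 21L)
  expect_equal(peak_length(h("21" = 10, "27" = 10)), 21L)
  expect_equal(peak_length(h("25" = 40)), 25L)
  expect_error(peak_length(integer(0)), "non-empty")
})

test_that("the peak-dominance rule assigns endo-siRNA and piRNA labels", {
  cfg <- class_config("nonbilaterian")
  expect_equal(classify_by_peak(h("20" = 5, "21" = 30, "22" = 10,
                                  "26" = 8), cfg), "endo_siRNA")
  expect_equal(classify_by_peak(h("27" = 50, "28" = 20, "26" = 10,
                                  "21" = 5), cfg), "piRNA")
  # peak 26: halo (25,26,27) = 25 > remaining 20
  expect_equal(classify_by_peak(h("21" = 10, "22" = 10, "26" = 25), cfg),
               "piRNA")
  expect_equal(classify_by_peak(h("21" = 10, "22" = 10, "26" = 25),
                                class_config("drosophila")), "piRNA")
})

test_that("dominance is strict: equality or boosted off-peak unclassifies", {
  cfg <- class_config("nonbilaterian")
  expect_equal(classify_by_peak(h("21" = 10, "27" = 10), cfg),
               "unclassified")
  endo <- h("20" = 5, "21" = 30, "22" = 10, "26" = 8)
  expect_equal(classify_by_peak(endo, cfg), "endo_siRNA")
  # boosted off-peak counts outweigh the 20-22 halo while 21 stays the peak
  flipped <- h("21" = 30, "22" = 10, "26" = 25, "30" = 25)
  expect_equal(classify_by_peak(flipped, cfg), "unclassified")
})

test_that("HU Dicer-length clusters are routed to candidate review", {
  cfg <- class_config("nonbilaterian")
  endo <- h("21" = 40, "22" = 5)
  expect_equal(classify_by_peak(endo, cfg, is_hu = TRUE),
               "miRNA_candidate_HU")
  expect_equal(classify_by_peak(endo, cfg, is_hu = FALSE), "endo_siRNA")
  relaxed <- class_config("nonbilaterian", apply_hu_filter = FALSE)
  expect_equal(classify_by_peak(endo, relaxed, is_hu = TRUE), "endo_siRNA")
})

test_that("the 26-nt peak is disambiguated by peak-set mass, tie to piRNA", {
  cfg <- class_config("mnemiopsis")
  expect_equal(classify_by_peak(h("26" = 20, "24" = 10, "25" = 5), cfg),
               "mer25")
  expect_equal(classify_by_peak(h("26" = 20, "27" = 10, "28" = 5), cfg),
               "piRNA")
  expect_equal(classify_by_peak(h("26" = 20), cfg), "piRNA")
})

test_that("known-locus annotation takes precedence in the stated order", {
  set.seed(12)
  cl <- build_clusters(mk_reads("sc1", c(0L, 20L, 40L, 500L, 520L, 540L,
                                         1000L, 1020L, 1040L), 21L))
  tracks <- list(
    known_miRNA = annotation_track("sc1", 0L, 80L,
                                   element_class = "known_miRNA"),
    tRNA = annotation_track("sc1", c(0L, 500L), c(80L, 600L),
                            element_class = "tRNA"),
    snoRNA = annotation_track("sc1", c(500L, 1000L), c(600L, 1100L),
                              element_class = "snoRNA")
  )
  out <- annotate_known_loci(cl, tracks)
  expect_identical(S4Vectors::mcols(out)$class,
                   c("known_miRNA", "tRNA", "snoRNA"))
  none <- annotate_known_loci(cl, list())
  expect_true(all(is.na(S4Vectors::mcols(none)$class)))
})

# deliberately different formulation of the printed rule, used as the oracle
oracle_label <- function(hist, cfg, is_hu = FALSE) {
  lens <- as.integer(names(hist))
  cnt <- as.numeric(hist)
  L <- min(lens[cnt == max(cnt)])
  inside <- abs(lens - L) <= 1
  if (sum(cnt[inside]) <= sum(cnt[!inside])) return("unclassified")
  labs <- character(0)
  if (L %in% cfg$endo_peaks) {
    labs <- c(labs, if (is_hu && cfg$apply_hu_filter) "miRNA_candidate_HU"
              else "endo_siRNA")
  }
  if (L %in% cfg$pirna_peaks) labs <- c(labs, "piRNA")
  if (L %in% cfg$mer25_peaks) labs <- c(labs, "mer25")
  if (length(labs) == 0) return("unclassified")
  if (length(labs) == 1) return(labs)
  if (sum(cnt[lens %in% cfg$mer25_peaks]) >
      sum(cnt[lens %in% cfg$pirna_peaks])) "mer25" else "piRNA"
}

test_that("classification matches the independent oracle on random histograms", {
  set.seed(13)
  for (preset in c("nonbilaterian", "drosophila", "mnemiopsis")) {
    cfg <- class_config(preset)
    for (i in 1:300) {
      k <- sample(2:8, 1)
      lens <- sort(sample(15:32, k))
      cnt <- stats::rpois(k, 8) + 1L
      hist <- stats::setNames(cnt, lens)
      is_hu <- stats::runif(1) < 0.3
      expect_identical(classify_by_peak(hist, cfg, is_hu),
                       oracle_label(hist, cfg, is_hu),
                       info = paste(preset, paste(lens, cnt, collapse = " ")))
    }
  }
})

test_that("class labels are exclusive and exhaustive over a library", {
  cl <- shared_classified()
  lab <- as.character(S4Vectors::mcols(cl)$class)
  expect_false(anyNA(lab))
  expect_true(all(lab %in% c("known_miRNA", "miRNA_candidate_HU", "tRNA",
                             "snoRNA", "endo_siRNA", "piRNA", "mer25",
                             "unclassified")))
})

test_that("class tabulation splits unique and multi-mapping clusters", {
  set.seed(14)
  uni <- mk_reads("sc1", c(0L, 15L, 30L), c(21L, 21L, 22L),
                  count = c(2L, 1L, 1L))
  multi <- mk_reads("sc1", c(500L, 515L, 530L), c(27L, 27L, 28L),
                    nmap = c(3L, 1L, 1L))
  cl <- classify_clusters(build_clusters(c(uni, multi)),
                          config = class_config("nonbilaterian"))
  tab <- tabulate_classes(list(libA = cl))
  expect_equal(tab$unique_endo_siRNA, 1)
  expect_equal(tab$multi_endo_siRNA, 0)
  expect_equal(tab$multi_piRNA, 1)  # one multimapper taints the cluster
  expect_equal(tab$unique_piRNA, 0)

  empty <- classify_clusters(build_clusters(mk_reads("sc1", integer(0),
                                                     integer(0))))
  tab0 <- tabulate_classes(list(none = empty))
  expect_true(all(tab0[, -1] == 0))
})
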