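test_that("reads merge transitively at gaps up to the window, split beyond", {
  set.seed(6)
  # three 21-nt reads with 10-nt gaps: one cluster spanning 83 bp
  r <- mk_reads("sc1", c(0L, 31L, 62L), 21L)
  cl <- build_clusters(r, window = 150L)
  expect_length(cl, 1)
  expect_equal(GenomicRanges::width(cl), 83L)

  # the gap boundary: 150 merges, 151 splits (min thresholds relaxed to
  # observe the merge itself)
  two <- function(gap) {
    r <- mk_reads("sc1", c(0L, 21L + gap), 21L)
    length(build_clusters(r, window = 150L, min_distinct = 1L,
                          min_cluster_len = 1L))
  }
  expect_equal(two(150L), 1)
  expect_equal(two(151L), 2)
})

test_that("clusters need >= 3 distinct non-perfectly-overlapping reads and >= 51 bp", {
  set.seed(7)
  expect_length(build_clusters(mk_reads("sc1", c(0L, 40L), 21L)), 0)

  # three distinct sequences on identical intervals are perfectly
  # overlapping: rejected regardless of their number
  same_iv <- mapped_reads(rep("sc1", 3), rep(0L, 3), rep(60L, 3),
                          rep("+", 3), rand_seq(rep(60L, 3)),
                          count = c(1L, 1L, 1L), n_mappings = rep(1L, 3))
  expect_length(build_clusters(same_iv), 0)

  # span 45 bp < 51 bp: discarded
  short <- mk_reads("sc1", c(0L, 12L, 24L), 21L)
  expect_equal(max(bed0_end <- GenomicRanges::end(short)) -
                 min(GenomicRanges::start(short) - 1L), 45L)
  expect_length(build_clusters(short), 0)

  # same layout stretched past 51 bp: kept
  expect_length(build_clusters(mk_reads("sc1", c(0L, 20L, 40L), 21L)), 1)
})

test_that("uniformity index reproduces the 16/3 and 16/12 worked examples", {
  set.seed(8)
  hu <- mk_reads("sc1", c(0L, 25L, 50L), 21L, count = c(10L, 4L, 2L))
  cl <- build_clusters(hu)
  expect_equal(S4Vectors::mcols(cl)$total_count, 16L)
  expect_equal(S4Vectors::mcols(cl)$distinct_reads, 3L)
  expect_equal(round(compute_uniformity_index(cl), 1), 5.3)

  lu <- mk_reads("sc1", seq(0L, 55L, by = 5L), 21L,
                 count = c(rep(2L, 4), rep(1L, 8)))
  cl2 <- build_clusters(lu)
  expect_equal(S4Vectors::mcols(cl2)$distinct_reads, 12L)
  expect_equal(S4Vectors::mcols(cl2)$total_count, 16L)
  expect_equal(round(compute_uniformity_index(cl2), 1), 1.3)
})

test_that("UI is >= 1 with equality exactly for all-singleton clusters", {
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    counts <- sample(1:6, n, replace = TRUE)
    r <- mk_reads("sc1", cumsum(c(0L, rep(10L, n - 1))), 21L,
                  count = counts)
    cl <- build_clusters(r)
    ui <- compute_uniformity_index(cl)
    expect_gte(ui, 1)
    expect_equal(ui == 1, all(counts == 1))
  }
})

test_that("cluster calls are independent of read input order", {
  set.seed(10)
  r <- mk_reads("sc1", sort(sample(0:3000, 40)), sample(20:28, 40, TRUE),
                count = sample(1:9, 40, TRUE))
  a <- build_clusters(r)
  b <- build_clusters(r[sample(length(r))])
  expect_equal(GenomicRanges::granges(a), GenomicRanges::granges(b))
  expect_identical(S4Vectors::mcols(a)$ui, S4Vectors::mcols(b)$ui)
  expect_identical(as.list(S4Vectors::mcols(a)$length_hist),
                   as.list(S4Vectors::mcols(b)$length_hist))
})

test_that("UI normalisation follows its definition and rejects zero depth", {
  expect_equal(normalize_ui(16 / 3, 1e6), (16 / 3) / 1e6)
  expect_equal(normalize_ui(1, 250), 1 / 250)
  expect_error(normalize_ui(2, 0), "positive")
})

test_that("HU/LU segregation is a total partition at the threshold", {
  set.seed(11)
  hu <- mk_reads("sc1", c(0L, 25L, 50L), 21L, count = c(10L, 4L, 2L))
  lu <- mk_reads("sc1", seq(3000L, 3055L, by = 5L), 21L,
                 count = c(rep(2L, 4), rep(1L, 8)))
  cl <- build_clusters(c(hu, lu))
  seg <- segregate_hu_lu(cl, threshold = 3)
  expect_length(seg$hu, 1)
  expect_length(seg$lu, 1)
  expect_gte(S4Vectors::mcols(seg$hu)$ui, 3)
  expect_lt(S4Vectors::mcols(seg$lu)$ui, 3)
  expect_equal(length(seg$hu) + length(seg$lu), length(cl))

  singles <- build_clusters(mk_reads("sc1", c(0L, 25L, 50L), 21L))
  seg2 <- segregate_hu_lu(singles, threshold = 1.0001)
  expect_length(seg2$hu, 0)
  expect_error(segregate_hu_lu(cl, threshold = 1), "exceed 1")
})

test_that("raw UI grows with depth while normalised UI stays comparable", {
  sim <- shared_sim()
  mirna_ui <- function(scale, seed) {
    lib <- simulate_library(sim, rng_seed = seed, depth_scale = scale)
    cl <- build_clusters(exclude_rrna(filter_multimappers(lib)$all_reads,
                                      sim$tracks$rRNA))
    hit <- GenomicRanges::countOverlaps(cl, sim$tracks$known_miRNA,
                                        ignore.strand = TRUE) > 0
    list(ui = mean(S4Vectors::mcols(cl)$ui[hit]),
         norm = mean(normalize_ui(S4Vectors::mcols(cl)$ui[hit],
                                  library_depth(lib))))
  }
  shallow <- mirna_ui(1, 501)
  deep <- mirna_ui(5, 502)
  expect_gt(deep$ui, shallow$ui)
  # normalisation removes most of the depth effect
  expect_lt(abs(log(deep$norm / shallow$norm)),
            abs(log(deep$ui / shallow$ui)))
})
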