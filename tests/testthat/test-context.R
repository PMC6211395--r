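test_that("transposon masking removes genic intervals at 1-nt overlap", {
  tracks <- list(
    exon = annotation_track("sc1", c(0L, 300L, 598L), c(100L, 400L, 700L),
                            element_class = "exon"),
    transposon_known = annotation_track("sc1", c(99L, 400L), c(250L, 599L),
                                        element_class = "transposon_known")
  )
  masked <- mask_genic_by_transposon(tracks)
  # exons overlapping a transposon by 1 nt (at 99 and at 598) are removed;
  # the exon abutting the transposon end at 400 (half-open) is kept
  starts <- GenomicRanges::start(masked$exon) - 1L
  expect_identical(starts, 300L)
  expect_length(masked$transposon_known, 2)

  no_tp <- mask_genic_by_transposon(tracks["exon"])
  expect_identical(no_tp$exon, tracks$exon)
})

test_that("the 51% rule assigns contexts and leaves 50% intergenic", {
  cl <- GenomicRanges::GRanges("sc1", IRanges::IRanges(c(1, 1001, 2001),
                                                       width = 100))
  S4Vectors::mcols(cl)$cluster_id <- c("a", "b", "c")
  tracks <- list(exon = annotation_track(
    "sc1", c(0L, 1000L, 2000L), c(60L, 1050L, 2051L),
    element_class = "exon"))
  asg <- assign_context(cl, tracks)
  expect_identical(asg$context, c("exon", "intergenic", "exon"))
  expect_equal(asg$max_fraction, c(0.60, 0.50, 0.51))
})

test_that("clusters may satisfy several element classes at once", {
  cl <- GenomicRanges::GRanges("sc1", IRanges::IRanges(1, width = 100))
  S4Vectors::mcols(cl)$cluster_id <- "a"
  tracks <- list(
    exon = annotation_track("sc1", 0L, 60L, element_class = "exon"),
    transposon_known = annotation_track("sc1", 30L, 90L,
                                        element_class = "transposon_known"))
  asg <- assign_context(cl, tracks)
  expect_identical(asg$contexts, "exon,transposon_known")
  expect_identical(asg$context, "exon")  # precedence for the single label

  # min_fraction = 0 degenerates to any-overlap
  tiny <- list(exon = annotation_track("sc1", 99L, 110L,
                                       element_class = "exon"))
  expect_identical(assign_context(cl, tiny)$context, "intergenic")
  expect_identical(assign_context(cl, tiny, min_fraction = 1e-9)$context,
                   "exon")
})

test_that("genome coverage uses interval unions and validates bounds", {
  gl <- c(sc1 = 1000)
  one <- list(exon = annotation_track("sc1", 100L, 200L,
                                      element_class = "exon"))
  expect_equal(genome_coverage(one, gl)$percent, 10)

  two <- list(exon = annotation_track("sc1", c(0L, 50L), c(100L, 150L),
                                      element_class = "exon"))
  expect_equal(genome_coverage(two, gl)$bp, 150)

  empty <- list(intron = annotation_track("sc1", integer(0), integer(0),
                                          element_class = "intron")[0])
  expect_equal(genome_coverage(empty, gl)$percent, 0)

  beyond <- list(exon = annotation_track("sc1", 900L, 1100L,
                                         element_class = "exon"))
  expect_error(genome_coverage(beyond, gl), "beyond")
})

test_that("coverage of the union of all tracks never exceeds the genome", {
  sim <- shared_sim()
  all_iv <- unlist(GenomicRanges::GRangesList(
    lapply(sim$tracks[lengths(sim$tracks) > 0], GenomicRanges::granges)))
  pooled <- list(gene_model = all_iv)
  S4Vectors::metadata(pooled$gene_model)$element_class <- "gene_model"
  cov <- genome_coverage(pooled, sim$scaffold_lengths)
  expect_lte(cov$percent, 100)
})

test_that("overlap enrichment handles identity and empty references", {
  gl <- c(sc1 = 50000)
  cl <- GenomicRanges::GRanges("sc1", IRanges::IRanges(
    seq(1000, 40000, by = 4000), width = 300))
  self <- overlap_enrichment_test(cl, cl, gl, 200, rng_seed = 31)
  expect_equal(self$observed, length(cl))
  expect_equal(self$p, 1 / 201)

  none <- overlap_enrichment_test(
    cl, GenomicRanges::GRanges(), gl, 200, rng_seed = 32)
  expect_equal(none$observed, 0)
  expect_equal(none$p, 1)
})

test_that("correlated layouts are called enriched, oversized clusters skip", {
  gl <- c(sc1 = 50000)
  cl <- GenomicRanges::GRanges("sc1", IRanges::IRanges(
    seq(1000, 40000, by = 4000), width = 300))
  ref <- GenomicRanges::shift(cl, 50)
  res <- overlap_enrichment_test(cl, ref, gl, 1000, rng_seed = 33)
  expect_lte(res$p, 0.01)

  big <- c(cl, GenomicRanges::GRanges("sc1", IRanges::IRanges(1, 60000)))
  expect_warning(overlap_enrichment_test(big, ref, gl, 200, rng_seed = 34),
                 "skipped")
})

test_that("cis-NAT prediction needs >= 1 nt antisense overlap, symmetric", {
  gm <- annotation_track("sc1",
                         c(100L, 199L, 300L, 350L, 600L, 700L),
                         c(200L, 300L, 450L, 450L, 700L, 800L),
                         strand = c("+", "-", "+", "+", "+", "-"),
                         element_class = "gene_model",
                         name = c("g1", "g2", "g3", "g4", "g5", "g6"))
  cis <- predict_cis_nats(gm)
  # g1/g2 overlap 1 nt antisense; g3/g4 same strand; g5/g6 abut half-open
  expect_setequal(cis, c("g1", "g2"))

  # symmetry on a random layout: every cis gene has a cis partner
  set.seed(35)
  starts <- sort(sample(0:5000, 40))
  rnd <- annotation_track("sc1", starts, starts + sample(100:400, 40, TRUE),
                          strand = sample(c("+", "-"), 40, TRUE),
                          element_class = "gene_model",
                          name = sprintf("g%02d", 1:40))
  cis <- predict_cis_nats(rnd)
  for (g in cis) {
    gi <- rnd[S4Vectors::mcols(rnd)$name == g]
    partners <- rnd[as.character(GenomicRanges::strand(rnd)) !=
                      as.character(GenomicRanges::strand(gi))]
    hit <- S4Vectors::mcols(partners)$name[
      GenomicRanges::countOverlaps(partners, gi, ignore.strand = TRUE) > 0]
    expect_true(all(hit %in% cis))
    expect_gt(length(hit), 0)
  }
})

test_that("cis-NAT cluster fractions follow the planted design", {
  gm <- annotation_track("sc1", c(0L, 300L, 5000L), c(500L, 800L, 5400L),
                         strand = c("+", "-", "+"),
                         element_class = "gene_model",
                         name = c("a", "b", "c"))
  cl <- GenomicRanges::GRanges("sc1", IRanges::IRanges(
    c(351, 5101, 9001), width = 100))
  res <- cis_nat_srna_fraction(cl, gm)
  expect_equal(res$gene_fraction, 2 / 3)
  # cluster 1 sits in the a/b overlap (cis), cluster 2 in gene c (not cis),
  # cluster 3 is intergenic and excluded from the denominator
  expect_equal(res$n_gene_clusters, 2L)
  expect_equal(res$cluster_fraction, 1 / 2)

  none <- cis_nat_srna_fraction(cl[0], gm[0])
  expect_equal(none$gene_fraction, 0)
  expect_equal(none$cluster_fraction, 0)
})
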