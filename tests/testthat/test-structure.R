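# exhaustive enumeration of nested pairings: the independent folding oracle
# for short sequences (first position unpaired, or paired with any legal j)
oracle_best_score <- function(s, min_loop = 3) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  w <- function(a, b) {
    p <- paste0(a, b)
    if (p %in% c("GC", "CG")) 1
    else if (p %in% c("AU", "UA")) 0.7
    else if (p %in% c("GU", "UG")) 0.5
    else 0
  }
  rec <- function(a, b) {
    if (b - a < min_loop + 1) return(0)
    best <- rec(a + 1, b)
    for (j in (a + min_loop + 1):b) {
      ww <- w(ch[a], ch[j])
      if (ww == 0) next
      best <- max(best, ww + rec(a + 1, j - 1) + rec(j + 1, b))
    }
    best
  }
  rec(1, length(ch))
}

test_that("folding returns zero for unpairable and full stems for hairpins", {
  f0 <- fold_mfe("AAAAAAAAAA")
  expect_equal(f0$mfe, 0)
  expect_equal(f0$structure, strrep(".", 10))

  hp <- paste0(strrep("G", 20), "AAAA", strrep("C", 20))
  f <- fold_mfe(hp)
  expect_equal(f$mfe, -20)
  expect_equal(sum(strsplit(f$structure, "")[[1]] %in% c("(", ")")), 40)
  expect_identical(fold_mfe(hp), f)  # deterministic
  expect_error(fold_mfe("ACGUN"), "non-ACGU")
})

test_that("the engine matches exhaustive enumeration on short sequences", {
  set.seed(20)
  for (i in 1:15) {
    s <- rand_seq(sample(10:14, 1))
    expect_equal(-fold_mfe(s)$mfe, oracle_best_score(s), tolerance = 1e-9,
                 info = s)
  }
})

test_that("strand selection folds the read strand, else the lower MFE", {
  # frozen sequence whose two strands fold differently (GU-pair asymmetry):
  # plus -11.3, reverse complement -10.2 under the built-in engine
  s <- "CUGGGAGCGUGGAGUGUGCGUGCCCGUUCUAGGGUAUAAU"
  expect_lt(fold_mfe(s)$mfe, fold_mfe(rc_rna(s))$mfe)
  genome <- Biostrings::DNAStringSet(c(sc1 = chartr("U", "T", rc_rna(s))))

  cl <- GenomicRanges::GRanges("sc1", IRanges::IRanges(1, 40))
  S4Vectors::mcols(cl)$strands <- "+-"
  both <- select_fold_strand(cl, genome)
  expect_equal(both$strand, "-")  # minus strand is the stronger fold
  expect_equal(both$mfe, fold_mfe(s)$mfe)

  S4Vectors::mcols(cl)$strands <- "+"
  plus <- select_fold_strand(cl, genome)
  expect_equal(plus$strand, "+")
  expect_equal(plus$mfe, fold_mfe(rc_rna(s))$mfe)

  # reverse-complement palindrome: equal MFEs, the tie goes to plus
  pal <- strrep("GGAAUUCC", 3)
  expect_identical(pal, rc_rna(pal))
  gpal <- Biostrings::DNAStringSet(c(sc1 = chartr("U", "T", pal)))
  clp <- GenomicRanges::GRanges("sc1", IRanges::IRanges(1, nchar(pal)))
  S4Vectors::mcols(clp)$strands <- "+-"
  expect_equal(select_fold_strand(clp, gpal)$strand, "+")

  expect_error(select_fold_strand(cl, gpal["sc1"][0]), "absent")
})

test_that("dinucleotide shuffling preserves composition exactly", {
  din <- function(x) {
    p <- strsplit(x, "", fixed = TRUE)[[1]]
    table(paste0(p[-length(p)], p[-1]))
  }
  set.seed(21)
  for (i in 1:50) {
    s <- rand_seq(sample(20:80, 1))
    sh <- dinucleotide_shuffle(s)
    expect_equal(nchar(sh), nchar(s))
    expect_identical(din(sh), din(s), info = s)
  }
  expect_identical(dinucleotide_shuffle("AC"), "AC")
  s <- rand_seq(60L)
  expect_identical(dinucleotide_shuffle(s, rng_seed = 9L),
                   dinucleotide_shuffle(s, rng_seed = 9L))
})

test_that("shuffled sequences are usually different from the input", {
  set.seed(22)
  s <- rand_seq(60L)
  out <- vapply(1:20, function(i) dinucleotide_shuffle(s), character(1))
  expect_gt(length(unique(out)), 10)
})

test_that("randfold p-values obey the add-one formula and its bounds", {
  # homopolymer: every shuffle is the sequence itself
  expect_equal(randfold_test(strrep("A", 40), 20, rng_seed = 1)$p, 1)

  set.seed(23)
  hp <- mk_hairpin(25)
  r <- randfold_test(hp, 100, rng_seed = 2)
  expect_gte(r$p, 1 / 101)
  expect_lte(r$p, 1)
  # a strong random-arm hairpin beats nearly every shuffle
  expect_lte(r$p, 0.02)
  # with a single shuffle the only possible values are 1/2 and 1
  one <- randfold_test(hp, 1, rng_seed = 3)$p
  expect_equal(one, 0.5)
  expect_error(randfold_test(hp, 0), "n_shuffles")
})

test_that("enrichment curves separate structured from unstructured classes", {
  cl <- GenomicRanges::GRanges(rep("sc1", 8),
                               IRanges::IRanges(seq(1, 8000, by = 1000),
                                                width = 200))
  S4Vectors::mcols(cl)$class <- rep(c("endo_siRNA", "piRNA"), each = 4)
  S4Vectors::mcols(cl)$randfold_p <- c(0.009, 0.009, 0.04, 0.2,
                                       1, 1, 1, 1)
  curves <- structure_enrichment_curves(cl, focal_classes = "endo_siRNA")
  expect_equal(nrow(curves), 8)  # 4 cutoffs x (focal + background)
  endo <- curves[curves$class == "endo_siRNA", ]
  bg <- curves[curves$class == "background", ]
  expect_equal(endo$percent, c(50, 50, 75, 75))
  expect_true(all(bg$percent == 0))
})

test_that("the ViennaRNA backend plugs into the same contract", {
  hp <- paste0(strrep("G", 15), "AAAA", strrep("C", 15))
  f <- fold_mfe(hp, backend = "vienna")
  expect_lt(f$mfe, 0)
  expect_equal(nchar(f$structure), nchar(hp))
})
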