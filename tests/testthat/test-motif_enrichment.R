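test_that("k-mer presence counts sequences, not occurrences, and masks N", {
  cnt <- kmer_presence_counts(c("GGAGA", "TTTT"), 4)
  expect_equal(unname(cnt["GGAG"]), 1L)
  expect_equal(unname(cnt["GAGA"]), 1L)
  expect_equal(unname(cnt["TTTT"]), 1L)
  expect_equal(sum(cnt), 3L)
  # presence: GGAG occurs twice in one sequence but counts once
  cnt2 <- kmer_presence_counts("GGAGGAG", 4)
  expect_equal(unname(cnt2["GGAG"]), 1L)
  # every window of GGNAG contains the N
  expect_equal(sum(kmer_presence_counts("GGNAG", 4)), 0L)
  expect_warning(cnt3 <- kmer_presence_counts(c("ACG", "TT"), 4),
                 "exceeds")
  expect_equal(sum(cnt3), 0L)
})

test_that("all_kmers enumerates 4^k strings in lexicographic order", {
  k2 <- all_kmers(2)
  expect_length(k2, 16L)
  expect_equal(k2[1:5], c("AA", "AC", "AG", "AT", "CA"))
  expect_false(is.unsorted(k2))
})

test_that("enrichment p-values match the worked hypergeometric cases", {
  expect_equal(enrichment_test(3, 3, 0, 3), 0.05)
  expect_equal(enrichment_test(1, 10, 1, 10),
               1 - choose(18, 10) / choose(20, 10))
  expect_equal(enrichment_test(0, 10, 5, 10), 1.0)
  expect_error(enrichment_test(1, 0, 0, 3), "totals")
  expect_error(enrichment_test(4, 3, 0, 3), "inconsistent")
})

test_that("enrichment test equals exact tail summation on small tables", {
  set.seed(41)
  for (i in 1:400) {
    tt <- sample.int(20, 1); bt <- sample.int(20, 1)
    tw <- sample.int(tt + 1, 1) - 1L; bw <- sample.int(bt + 1, 1) - 1L
    p <- enrichment_test(tw, tt, bw, bt)
    o <- oracle_hyper_tail(tw, tt, bw, bt)
    expect_lt(abs(p - o) / o, 1e-10)
  }
})

test_that("swapping target and background gives the complementary tail", {
  # P_over(target) + P_over(background computed at one-less) = 1
  for (case in list(c(3, 8, 2, 9), c(5, 10, 1, 7), c(0, 4, 4, 6))) {
    tw <- case[1]; tt <- case[2]; bw <- case[3]; bt <- case[4]
    p_fwd <- enrichment_test(tw, tt, bw, bt)
    # lower tail of the same table: P(X <= tw) with margins fixed
    p_low <- phyper(tw, tw + bw, (tt - tw) + (bt - bw), tt)
    expect_equal(p_fwd + p_low -
                   dhyper(tw, tw + bw, (tt - tw) + (bt - bw), tt), 1)
  }
})

test_that("BH adjustment matches worked examples and rejects bad input", {
  expect_equal(bh_fdr(c(0.001, 0.02, 0.9)), c(0.003, 0.03, 0.9))
  expect_equal(bh_fdr(0.5), 0.5)
  expect_equal(bh_fdr(c(0.01, 0.01)), c(0.01, 0.01))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("BH matches the textbook step-up oracle on random vectors", {
  set.seed(42)
  for (i in 1:1000) {
    p <- runif(sample.int(30, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("GC-matched background matches bins, lengths and is seeded", {
  set.seed(43)
  genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 20000, TRUE),
                           collapse = ""))
  targets <- vapply(1:30, function(i) {
    # construct GC = 0.5, length 40 targets
    paste(rep(c("A", "G"), 20), collapse = "")
  }, "")
  bg <- sample_gc_matched_background(genome, targets, n_bg = 25, seed = 7)
  expect_s3_class(bg, "background_set")
  expect_length(bg$sequences, 25L)
  expect_true(all(nchar(bg$sequences) == 40L))
  gc <- vapply(bg$sequences, function(s)
    nchar(gsub("[^GC]", "", s)) / nchar(s), 0)
  expect_true(all(gc > 0.4 & gc <= 0.5))  # same 10-bin class as targets
  bg2 <- sample_gc_matched_background(genome, targets, n_bg = 25, seed = 7)
  expect_identical(bg$sequences, bg2$sequences)
  expect_error(sample_gc_matched_background(genome, targets, 0), "empty")
})

test_that("an unfillable GC bin raises an error naming the bin", {
  genome <- c(chr1 = strrep("AT", 2000))  # GC = 0 everywhere
  targets <- rep(strrep("GC", 20), 5)     # GC = 1
  expect_error(sample_gc_matched_background(genome, targets, 5,
                                            max_attempts = 50),
               "bin")
})

test_that("a planted motif with a clean background ranks first", {
  set.seed(44)
  base <- function() paste(sample(c("A", "C", "T"), 40, TRUE), collapse = "")
  targets <- vapply(1:40, function(i) {
    s <- base()
    paste0(substr(s, 1, 18), "GGAG", substr(s, 23, 40))
  }, "")
  bg <- background_from_sequences(vapply(1:40, function(i) base(), ""),
                                  "input_peaks")
  res <- discover_motifs(targets, bg, k = 4, fdr_cut = 0.001)
  expect_equal(res$kmer[res$rank == 1 & !is.na(res$rank)], "GGAG")
  expect_lt(res$q_value[res$kmer == "GGAG"], 0.001)
})

test_that("equal target/background proportions give p = 1 for a frequent kmer", {
  # a compositional confounder present in every sequence of both sets
  mk <- function() {
    s <- paste(sample(c("A", "C", "G", "T"), 36, TRUE), collapse = "")
    paste0("CTGG", s)
  }
  set.seed(45)
  targets <- vapply(1:30, function(i) mk(), "")
  bg <- background_from_sequences(vapply(1:30, function(i) mk(), ""))
  res <- discover_motifs(targets, bg, k = 4)
  row <- res[res$kmer == "CTGG", ]
  expect_equal(row$p_value, 1.0)
  expect_true(is.na(row$rank))
})

test_that("null target/background pairs yield essentially no discoveries", {
  set.seed(46)
  hits <- 0L
  for (i in 1:30) {
    seqs <- vapply(1:60, function(j)
      paste(sample(c("A", "C", "G", "T"), 36, TRUE), collapse = ""), "")
    res <- discover_motifs(seqs[1:30],
                           background_from_sequences(seqs[31:60]), k = 4)
    hits <- hits + sum(!is.na(res$rank))
  }
  expect_lte(hits / 30, 1)
})

test_that("significant kmers are ranked by percent with p tie-breaks", {
  set.seed(47)
  targets <- c(rep("AAAACCCC", 30), rep("AAAAGGGG", 10))
  bg <- background_from_sequences(rep("TTTTTTTT", 40))
  res <- discover_motifs(targets, bg, k = 4, fdr_cut = 0.05)
  sig <- res[!is.na(res$rank), ]
  expect_false(is.unsorted(sig$rank))
  expect_true(all(diff(sig$percent) <= 0))
  expect_equal(sig$kmer[1], "AAAA")  # percent 1.0 tops the list
})
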