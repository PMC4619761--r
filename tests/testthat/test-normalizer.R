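test_that("RPKM follows the reads-per-kb-per-million formula", {
  tx <- transcript_models(data.frame(
    chrom = "chr1", start = c(0L, 0L), end = c(2000L, 1000L), strand = "+",
    transcript_id = c("tA", "tB"), gene_id = c("gA", "gB")))
  # 100 reads on a 2 kb transcript in a 10M-read library -> RPKM 5
  e <- compute_rpkm(c(tA = 100), tx, 1e7)
  expect_equal(e$rpkm[e$transcript_id == "tA"], 5.0)
  expect_equal(e$rpkm[e$transcript_id == "tB"], 0)
  # 1 read / 1 kb / 1M -> 1.0
  e2 <- compute_rpkm(c(tB = 1), tx, 1e6)
  expect_equal(e2$rpkm[e2$transcript_id == "tB"], 1.0)
  expect_error(compute_rpkm(c(nope = 1), tx, 1e6), "nope")
  expect_error(compute_rpkm(c(tA = 1), tx, 0), "total_mapped_reads")
})

test_that("RPKM conservation: sum(rpkm * L) * total / 1e9 = exonic count", {
  set.seed(11)
  tx <- toy_transcripts()
  counts <- c(t1 = 137, t2 = 55)
  total <- 5e5
  e <- compute_rpkm(counts, tx, total)
  L <- tx$transcripts$exonic_length[match(e$transcript_id,
                                          tx$transcripts$transcript_id)]
  expect_equal(sum(e$rpkm * L) * total / 1e9, sum(counts))
})

test_that("per-transcript read counting is 5'-based, stranded, weighted", {
  tx <- toy_transcripts()
  reads <- aligned_reads(
    chrom = "chr1",
    start = c(150L, 195L, 350L, 750L, 750L, 120L),
    end = c(186L, 231L, 386L, 786L, 786L, 156L),
    strand = c("+", "+", "+", "-", "+", "-"))
  # read 2 starts at 195 (inside exon1), read 5 is + on a - transcript,
  # read 6 is - on a + transcript
  cnt <- count_reads_in_transcripts(reads, tx)
  expect_equal(unname(cnt["t1"]), 3)
  expect_equal(unname(cnt["t2"]), 1)
  w <- c(2, 1, 1, 5, 1, 1)
  cntw <- count_reads_in_transcripts(reads, tx, weights = w)
  expect_equal(unname(cntw["t1"]), 4)
  expect_equal(unname(cntw["t2"]), 5)
})

test_that("host transcript assignment follows the overlap tie rules", {
  tx <- transcript_models(data.frame(
    chrom = "chr1",
    start = c(100L, 100L, 500L),
    end = c(200L, 140L, 600L),
    strand = "+",
    transcript_id = c("t1", "t2", "t3"),
    gene_id = c("g1", "g2", "g3")))
  peaks <- data.frame(
    chrom = "chr1", start = c(110L, 130L, 900L), end = c(150L, 170L, 940L),
    strand = "+", stringsAsFactors = FALSE)
  host <- assign_host_transcript(peaks, tx)
  # peak 1: t1 overlap 40, t2 overlap 30 -> t1; peak 2: t1 40 vs t2 10 -> t1
  expect_equal(host, c("t1", "t1", NA))
  # exact tie on overlap -> longer exonic length, then lexicographic id
  tx2 <- transcript_models(data.frame(
    chrom = "chr1", start = c(100L, 100L), end = c(200L, 200L), strand = "+",
    transcript_id = c("tB", "tA"), gene_id = c("g1", "g2")))
  expect_equal(assign_host_transcript(
    data.frame(chrom = "chr1", start = 120L, end = 160L, strand = "+"),
    tx2), "tA")
})

make_scoring_fixture <- function() {
  tx <- transcript_models(data.frame(
    chrom = "chr1", start = 0L, end = 1000L, strand = "+",
    transcript_id = "t1", gene_id = "g1"))
  peaks <- data.frame(chrom = "chr1", start = 100L, end = 150L,
                      strand = "+", clip_count = 20,
                      threshold_used = 5L, stringsAsFactors = FALSE)
  attr(peaks, "peak_size") <- 50L
  list(tx = tx, peaks = peaks)
}

test_that("INPUT score matches the smoothed ratio worked example", {
  fx <- make_scoring_fixture()
  # 4 input reads inside the window, equal library sizes
  input <- aligned_reads("chr1", c(110L, 120L, 130L, 140L, 500L),
                         c(140L, 150L, 160L, 170L, 530L), "+")
  clip <- aligned_reads("chr1", rep(100L, 5), rep(136L, 5), "+")
  sc <- score_peaks(fx$peaks, "input", transcripts = fx$tx,
                    clip_reads = clip, input_reads = input, alpha = 1,
                    library_scaling = FALSE)
  # (20 + 1) / (4 + 1) = 4.2
  expect_equal(sc$score, 4.2)
  # with equal library sizes scaling must not change the value
  sc2 <- score_peaks(fx$peaks, "input", transcripts = fx$tx,
                     clip_reads = input, input_reads = input, alpha = 1,
                     library_scaling = TRUE)
  expect_equal(sc2$score, 4.2)
})

test_that("AVE-CLIP score matches the transcript-density worked example", {
  # c = 30, C_t = 300, w = 50, L_t = 1000 -> 30 / (15 + 1) = 1.875
  tx <- transcript_models(data.frame(
    chrom = "chr1", start = 0L, end = 1000L, strand = "+",
    transcript_id = "t1", gene_id = "g1"))
  peaks <- data.frame(chrom = "chr1", start = 100L, end = 150L,
                      strand = "+", clip_count = 30,
                      threshold_used = 5L, stringsAsFactors = FALSE)
  attr(peaks, "peak_size") <- 50L
  clip <- aligned_reads("chr1", rep(seq(0L, 960L, length.out = 300), 1L),
                        rep(seq(0L, 960L, length.out = 300), 1L) + 30L, "+")
  sc <- score_peaks(peaks, "ave_clip", transcripts = tx, clip_reads = clip,
                    alpha = 1)
  expect_equal(sc$score, 30 / (300 * 50 / 1000 + 1))
})

test_that("raw ranking breaks count ties by coordinate", {
  peaks <- data.frame(chrom = "chr1", start = c(100L, 900L, 400L),
                      end = c(150L, 950L, 450L), strand = "+",
                      clip_count = c(50, 7, 7), threshold_used = 5L,
                      stringsAsFactors = FALSE)
  sc <- score_peaks(peaks, "raw")
  expect_equal(sc$rank, 1:3)
  expect_equal(sc$start, c(100L, 400L, 900L))
})

test_that("missing context for a strategy is a named error", {
  fx <- make_scoring_fixture()
  expect_error(score_peaks(fx$peaks, "rpkm", transcripts = fx$tx),
               "requires")
  expect_error(score_peaks(fx$peaks, "input", transcripts = fx$tx),
               "input-RNA")
  expect_error(score_peaks(fx$peaks, "ave_clip", transcripts = fx$tx),
               "CLIP read set")
})

test_that("uniform input with equal depths reproduces the raw ranking", {
  set.seed(21)
  tx <- transcript_models(data.frame(
    chrom = "chr1", start = 0L, end = 5000L, strand = "+",
    transcript_id = "t1", gene_id = "g1"))
  starts <- sample.int(4900, 400) - 1L
  clip <- aligned_reads("chr1", starts, starts + 30L, "+")
  cfg <- peak_call_config(effective_genome_size = 5000, peak_size = 30,
                          fdr = 0.05)
  pk <- call_peaks(clip, cfg)
  # identical input count in every window: one input read per position
  ipos <- 0:4960
  input <- aligned_reads("chr1", ipos, ipos + 30L, "+")
  sc_raw <- score_peaks(pk, "raw")
  sc_in <- score_peaks(pk, "input", transcripts = tx, clip_reads = clip,
                       input_reads = input)
  key <- function(d) paste(d$chrom, d$start, d$strand)
  expect_equal(key(sc_in), key(sc_raw))
})

test_that("input/ave_input scores are library-scale invariant at alpha 0", {
  fx <- make_scoring_fixture()
  input <- aligned_reads("chr1", c(110L, 120L, 130L, 140L),
                         c(140L, 150L, 160L, 170L), "+")
  clip1 <- aligned_reads("chr1", rep(100L, 10), rep(136L, 10), "+")
  for (st in c("input", "ave_input")) {
    s1 <- score_peaks(fx$peaks, st, transcripts = fx$tx, clip_reads = clip1,
                      input_reads = input, alpha = 0)$score
    # triple both libraries: weights via copy_count
    clip3 <- aligned_reads("chr1", rep(100L, 10), rep(136L, 10), "+",
                           copy_count = 3L)
    input3 <- aligned_reads("chr1", c(110L, 120L, 130L, 140L),
                            c(140L, 150L, 160L, 170L), "+", copy_count = 3L)
    pk3 <- fx$peaks
    pk3$clip_count <- fx$peaks$clip_count * 3
    attr(pk3, "peak_size") <- 50L
    s3 <- score_peaks(pk3, st, transcripts = fx$tx, clip_reads = clip3,
                      input_reads = input3, weight_mode = "all_reads",
                      input_weight_mode = "all_reads", alpha = 0)$score
    expect_equal(s3, s1, tolerance = 1e-12)
  }
})

test_that("peaks without a host transcript rank last under rpkm", {
  tx <- toy_transcripts()
  peaks <- data.frame(chrom = "chr1",
                      start = c(120L, 5000L), end = c(160L, 5040L),
                      strand = "+", clip_count = c(5, 500),
                      threshold_used = 5L, stringsAsFactors = FALSE)
  attr(peaks, "peak_size") <- 40L
  expr <- compute_rpkm(c(t1 = 10), tx, 1e5)
  sc <- score_peaks(peaks, "rpkm", transcripts = tx, expression = expr)
  expect_true(sc$flagged[sc$start == 5000L])
  expect_equal(sc$rank[sc$start == 5000L], 2L)
  expect_true(is.na(sc$score[sc$start == 5000L]))
})

test_that("ranked peak tables are written sorted and reject bad ranks", {
  fx <- make_scoring_fixture()
  sc <- score_peaks(fx$peaks, "raw")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ranked_peaks(sc, f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 1L)
  expect_equal(names(tab), c("chrom", "start", "end", "strand", "clip_count",
                             "transcript_id", "strategy", "score", "rank"))
  sc2 <- rbind(sc, sc)  # duplicate rank 1
  expect_error(write_ranked_peaks(sc2, f), "duplicate ranks")
  # empty table -> header only
  write_ranked_peaks(sc[0, ], f)
  expect_equal(nrow(read.table(f, header = TRUE, sep = "\t")), 0L)
})
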