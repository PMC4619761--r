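# a small, fast configuration used throughout these tests
small_cfg <- function(seed = 5, ...) {
  defaults <- list(seed = seed, n_transcripts = 30L, n_true_sites = 60L,
                   clip_fragments = 8000L, input_reads = 8000L,
                   rnaseq_reads = 8000L, intergenic_gap = 3000L,
                   intron_length = c(500L, 1500L))
  do.call(clip_sim_config, utils::modifyList(defaults, list(...)))
}

test_that("genome and annotation generation is deterministic given a seed", {
  a <- simulate_genome_and_annotation(small_cfg())
  b <- simulate_genome_and_annotation(small_cfg())
  expect_identical(a$genome, b$genome)
  expect_identical(a$transcripts$exons, b$transcripts$exons)
  c <- simulate_genome_and_annotation(small_cfg(seed = 6))
  expect_false(identical(a$genome, c$genome))
})

test_that("confounder k-mers are enriched in exons over intergenic space", {
  sim <- simulate_genome_and_annotation(small_cfg())
  tx <- sim$transcripts
  ex_seq <- extract_sequence(sim$genome, genomic_intervals(
    tx$exons$chrom, tx$exons$start, tx$exons$end, strand = tx$exons$strand))
  # intergenic: take gaps between transcript spans
  spans <- do.call(rbind, lapply(split(tx$exons, tx$exons$transcript_id),
    function(e) data.frame(s = min(e$start), e = max(e$end))))
  spans <- spans[order(spans$s), ]
  gaps <- data.frame(s = head(spans$e, -1) + 100, e = spans$s[-1] - 100)
  gaps <- gaps[gaps$e - gaps$s > 200, ]
  ig_seq <- extract_sequence(sim$genome, genomic_intervals(
    "chr1", gaps$s, gaps$e, strand = "+"))
  rate <- function(seqs, kmer) {
    occ <- sum(vapply(seqs, function(s) {
      n <- nchar(s) - nchar(kmer) + 1
      sum(substring(s, 1:n, nchar(kmer):nchar(s)) == kmer)
    }, 0))
    occ / sum(nchar(seqs))
  }
  for (kmer in c("CTGG", "GCTG", "CCTG")) {
    expect_gt(rate(ex_seq, kmer), 2 * rate(ig_seq, kmer))
  }
})

test_that("annotation outputs agree across GTF and BED12", {
  sim <- simulate_genome_and_annotation(small_cfg())
  fg <- withr::local_tempfile(fileext = ".gtf")
  fb <- withr::local_tempfile(fileext = ".bed")
  write_gtf(sim$transcripts, fg)
  write_bed12(sim$transcripts, fb)
  tg <- read_transcripts(fg, "gtf_exon_subset")
  tb <- read_transcripts(fb, "bed12")
  expect_equal(tg$transcripts$exonic_length[
                 order(tg$transcripts$transcript_id)],
               tb$transcripts$exonic_length[
                 order(tb$transcripts$transcript_id)])
})

test_that("every planted site contains the motif on its strand", {
  sim <- simulate_clip_experiment(small_cfg())
  seqs <- extract_sequence(sim$genome, genomic_intervals(
    sim$sites$chrom, sim$sites$start, sim$sites$end,
    strand = sim$sites$strand))
  expect_true(all(seqs == "GGAG"))
  # sites do not overlap one another
  s <- sort(sim$sites$start)
  expect_true(all(diff(s) >= 4))
  # all sites lie within exons
  expect_equal(exonic_fraction(
    data.frame(chrom = sim$sites$chrom, start = sim$sites$start,
               end = sim$sites$end, strand = sim$sites$strand),
    sim$transcripts$exons), 1)
})

test_that("zero sites requested still yields a valid simulation", {
  sim <- simulate_clip_experiment(small_cfg(n_true_sites = 0L,
                                            signal_fraction = 0))
  expect_equal(nrow(sim$sites), 0L)
  expect_gt(nrow(sim$clip_reads), 0L)
})

test_that("full simulation is byte-identical across runs at a fixed seed", {
  a <- simulate_clip_experiment(small_cfg())
  b <- simulate_clip_experiment(small_cfg())
  expect_identical(a$genome, b$genome)
  expect_identical(a$clip_reads, b$clip_reads)
  expect_identical(a$input_reads, b$input_reads)
  expect_identical(a$rnaseq_reads, b$rnaseq_reads)
  expect_identical(a$sites, b$sites)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(a, d1); write_simulation(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("signal_fraction 1 without duplication puts all reads at sites", {
  sim <- simulate_clip_experiment(small_cfg(signal_fraction = 1,
                                            duplication_mean = 1))
  expect_true(all(sim$fragments$origin == "signal"))
  expect_true(all(sim$fragments$copies == 1L))
  expect_equal(nrow(sim$clip_reads), nrow(sim$fragments))
  # read 5' starts sit within jitter of their site centers
  p5 <- ifelse(sim$clip_reads$strand == "+", sim$clip_reads$start,
               sim$clip_reads$end - 1L)
  near <- vapply(p5, function(p) any(abs(sim$sites$center - p) <= 15), TRUE)
  expect_true(all(near))
})

test_that("geometric duplication reproduces the configured mean copy count", {
  sim <- simulate_clip_experiment(small_cfg(clip_fragments = 50000L))
  m <- nrow(sim$clip_reads) / nrow(sim$fragments)
  expect_lt(abs(m - 3) / 3, 0.05)
})

test_that("control reads track abundance and respect exon/intron layout", {
  cfg <- small_cfg(abundance_sdlog = 2)
  sim <- simulate_clip_experiment(cfg)
  # rnaseq reads never start in introns
  rn <- sim$rnaseq_reads
  p5 <- ifelse(rn$strand == "+", rn$start, rn$end - 1L)
  in_exon <- oracle_overlaps_any(
    data.frame(chrom = rn$chrom, start = p5, end = p5 + 1L),
    sim$transcripts$exons)
  expect_true(all(in_exon))
  # read-count ratio between two transcripts follows the abundance ratio
  cnt <- count_reads_in_transcripts(rn, sim$transcripts)
  ab <- sim$abundance[names(cnt)]
  big <- names(sort(ab, decreasing = TRUE))[1:2]
  expected <- sum(cnt) * ab[big] / sum(ab)
  expect_true(all(abs(cnt[big] - expected) <
                    4 * sqrt(expected) + 4))
  # input includes intronic reads
  ip <- sim$input_reads
  ip5 <- ifelse(ip$strand == "+", ip$start, ip$end - 1L)
  ip_exonic <- oracle_overlaps_any(
    data.frame(chrom = ip$chrom, start = ip5, end = ip5 + 1L),
    sim$transcripts$exons)
  expect_gt(mean(!ip_exonic), 0.3)
})

test_that("RPKM from simulated RNAseq recovers configured abundances", {
  sim <- simulate_clip_experiment(clip_sim_config(seed = 9))
  counts <- count_reads_in_transcripts(sim$rnaseq_reads, sim$transcripts)
  expr <- compute_rpkm(counts, sim$transcripts, nrow(sim$rnaseq_reads))
  rho <- cor(expr$rpkm, sim$abundance[expr$transcript_id],
             method = "spearman")
  expect_gt(rho, 0.95)
})

test_that("a paired simulation shares gene-level affinities", {
  simA <- simulate_clip_experiment(small_cfg())
  st <- simA$sites[, c("gene_id", "affinity")]
  simB <- simulate_clip_experiment(small_cfg(seed = 99), site_table = st)
  expect_equal(nrow(simB$sites), nrow(simA$sites))
  expect_equal(sort(simB$sites$affinity), sort(simA$sites$affinity))
  byg <- function(s) tapply(s$affinity, s$gene_id, max)
  a <- byg(simA$sites); b <- byg(simB$sites)
  expect_equal(a[sort(names(a))], b[sort(names(b))])
  expect_false(identical(simA$genome, simB$genome))
})
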