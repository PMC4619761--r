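# Independent oracles used by the property tests. These are deliberately
# naive (loops, direct summation) and never call the implementation paths
# they check.

# Poisson upper tail P(X >= k) by term-by-term pmf summation (log-space terms)
oracle_poisson_tail <- function(k, lambda, tol = 1e-18) {
  if (k <= 0) return(1)
  total <- 0
  i <- k
  repeat {
    term <- exp(i * log(lambda) - lambda - lgamma(i + 1))
    total <- total + term
    i <- i + 1
    if (term < tol * max(total, .Machine$double.xmin) && i > lambda + k) break
    if (i > k + 10000) break
  }
  total
}

# pure-tail Poisson FDR threshold by linear scan using the oracle tail
oracle_pure_tail_threshold <- function(lambda, fdr) {
  k <- 1
  while (oracle_poisson_tail(k, lambda) > fdr) k <- k + 1
  k
}

# hypergeometric upper-tail p-value by direct summation of choose() products
# (margins <= 40 keep every term an exact integer in double precision)
oracle_hyper_tail <- function(target_with, target_total, bg_with, bg_total) {
  m <- target_with + bg_with           # sequences containing the k-mer
  n <- (target_total - target_with) + (bg_total - bg_with)
  k <- target_total                    # draws
  xs <- target_with:min(m, k)
  xs <- xs[k - xs <= n]
  sum(choose(m, xs) * choose(n, k - xs)) / choose(m + n, k)
}

# textbook Benjamini-Hochberg step-up, written independently of p.adjust
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  # enforce monotonicity from the largest p downwards
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# exhaustive O(reads x windows) peak caller: scan every candidate anchor,
# threshold, then greedy selection with explicit loops
oracle_call_peaks <- function(reads, weights, peak_size, k_star, min_dist,
                              strand_specific = TRUE) {
  p5 <- ifelse(reads$strand == "+", reads$start, reads$end - 1L)
  sgrp <- if (strand_specific) reads$strand else rep(".", nrow(reads))
  cand <- data.frame(chrom = character(), start = integer(),
                     strand = character(), count = numeric())
  for (key in unique(paste(reads$chrom, sgrp))) {
    ix <- which(paste(reads$chrom, sgrp) == key)
    for (a in sort(unique(p5[ix]))) {
      cnt <- 0
      for (j in ix) if (p5[j] >= a && p5[j] < a + peak_size) {
        cnt <- cnt + weights[j]
      }
      cand <- rbind(cand, data.frame(chrom = reads$chrom[ix[1]], start = a,
                                     strand = sgrp[ix[1]], count = cnt))
    }
  }
  cand <- cand[cand$count >= k_star, , drop = FALSE]
  srank <- match(cand$strand, c("+", "-", "."))
  cand <- cand[order(-cand$count, cand$chrom, cand$start, srank), ,
               drop = FALSE]
  keep <- rep(FALSE, nrow(cand))
  if (nrow(cand)) {
    for (i in seq_len(nrow(cand))) {
      ok <- TRUE
      for (j in which(keep)) {
        if (cand$chrom[j] == cand$chrom[i] &&
            cand$strand[j] == cand$strand[i] &&
            abs(cand$start[j] - cand$start[i]) < min_dist) ok <- FALSE
      }
      keep[i] <- ok
    }
  }
  out <- cand[keep, , drop = FALSE]
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

# all-pairs interval overlap check (half-open intervals)
oracle_overlaps_any <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & a$start[i] < b$end & b$start < a$end[i])
  }, TRUE)
}

# small random aligned-read set on a toy genome
random_reads <- function(n, chroms = c("chr1", "chr2"), span = 2000L,
                         read_len = 30L) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(span, n, replace = TRUE) - 1L
  aligned_reads(chrom, start, start + read_len,
                sample(c("+", "-"), n, replace = TRUE))
}

# tiny deterministic transcript set: two transcripts on chr1
toy_transcripts <- function() {
  transcript_models(data.frame(
    chrom = "chr1",
    start = c(100L, 300L, 700L),
    end = c(200L, 400L, 900L),
    strand = c("+", "+", "-"),
    transcript_id = c("t1", "t1", "t2"),
    gene_id = c("g1", "g1", "g2"),
    stringsAsFactors = FALSE))
}
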