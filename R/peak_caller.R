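#' Peak-calling configuration
#'
#' @param effective_genome_size effective (mappable) genome size in bp
#' @param peak_size fixed peak width in bp; 0 selects it automatically as the
#'   median mapped-read span
#' @param fdr false discovery rate for the read-count threshold (default 0.001)
#' @param strand_specific scan each strand separately (default TRUE)
#' @param min_distance minimum distance between accepted peak starts on one
#'   chrom/strand; defaults to `peak_size`
#' @return a `peak_call_config` list
#' @export
peak_call_config <- function(effective_genome_size, peak_size = 0L,
                             fdr = 0.001, strand_specific = TRUE,
                             min_distance = NULL) {
  if (!is.numeric(effective_genome_size) || effective_genome_size <= 0) {
    stop("effective_genome_size must be > 0")
  }
  if (peak_size < 0) stop("peak_size must be >= 0")
  if (fdr <= 0 || fdr >= 1) stop("fdr must be in (0, 1)")
  structure(list(effective_genome_size = as.numeric(effective_genome_size),
                 peak_size = as.integer(peak_size), fdr = fdr,
                 strand_specific = isTRUE(strand_specific),
                 min_distance = if (is.null(min_distance)) NULL
                                else as.integer(min_distance)),
            class = "peak_call_config")
}

#' Choose the peak size from the mapped-read length distribution
#'
#' @param reads aligned-read data.frame
#' @return the median mapped-read span, rounded to the nearest integer
#' @export
choose_peak_size <- function(reads) {
  if (nrow(reads) == 0) stop("cannot choose a peak size from zero reads")
  as.integer(round(median(reads$end - reads$start)))
}

#' Expected background read count per scanning window
#'
#' Under a global uniform background, the Poisson rate per window of width
#' `peak_size` is `total_weighted_reads * peak_size / G`, with
#' `G = 2 * effective_genome_size` when each strand is scanned separately.
#'
#' @param total_weighted_reads total (weighted) mapped reads
#' @param peak_size window width in bp
#' @param effective_genome_size effective genome size in bp
#' @param strand_specific whether strands are scanned separately
#' @return the Poisson rate lambda per window
#' @export
estimate_background_rate <- function(total_weighted_reads, peak_size,
                                     effective_genome_size,
                                     strand_specific = TRUE) {
  if (total_weighted_reads <= 0 || peak_size <= 0 ||
      effective_genome_size <= 0) {
    stop("all arguments must be positive")
  }
  G <- if (isTRUE(strand_specific)) 2 * effective_genome_size
       else effective_genome_size
  total_weighted_reads * peak_size / G
}

#' Poisson/FDR read-count threshold
#'
#' Selects the smallest integer count `k*` whose estimated false discovery
#' rate falls at or below `fdr`. With observed candidate-window tail counts,
#' the FDR estimate at `k` is the ratio of expected windows
#' `n_windows * P(X >= k; lambda)` to observed windows with count `>= k`
#' (HOMER-style expected/observed ratio). Without observed counts the rule is
#' the pure Poisson tail `P(X >= k; lambda) <= fdr`.
#'
#' @param lambda background Poisson rate per window
#' @param n_windows number of scanned windows genome-wide (required for the
#'   expected/observed rule)
#' @param observed_tail_counts integer vector; element `k` is the number of
#'   candidate windows with count `>= k`. NULL selects the pure-tail rule.
#' @param fdr target false discovery rate
#' @return integer threshold `k*`; if no `k` attains the target before the
#'   Poisson tail underflows, the last representable `k` is returned with a
#'   warning
#' @export
poisson_fdr_threshold <- function(lambda, n_windows = NULL,
                                  observed_tail_counts = NULL, fdr = 0.001) {
  if (lambda <= 0) stop("lambda must be > 0")
  if (fdr <= 0 || fdr >= 1) stop("fdr must be in (0, 1)")
  k_cap <- 10L
  tail_at <- function(k) ppois(k - 1, lambda, lower.tail = FALSE)
  while (tail_at(k_cap) > 0 && k_cap < 100000L) k_cap <- k_cap * 2L
  k <- 1:k_cap
  tails <- tail_at(k)
  k_max <- if (any(tails == 0)) min(which(tails == 0)) - 1L else k_cap
  if (k_max < 1L) return(1L)
  k <- k[seq_len(k_max)]
  tails <- tails[seq_len(k_max)]
  if (is.null(observed_tail_counts) || !length(observed_tail_counts)) {
    ok <- which(tails <= fdr)
  } else {
    if (is.null(n_windows) || n_windows <= 0) {
      stop("n_windows required for the expected/observed FDR rule")
    }
    obs <- rep(0, k_max)
    m <- min(k_max, length(observed_tail_counts))
    obs[seq_len(m)] <- observed_tail_counts[seq_len(m)]
    if (any(diff(observed_tail_counts) > 0)) {
      stop("observed_tail_counts must be non-increasing in k")
    }
    fdr_hat <- n_windows * tails / pmax(obs, 1)
    ok <- which(fdr_hat <= fdr)
  }
  if (!length(ok)) {
    warning("no count threshold attains the target FDR; returning k_max = ",
            k_max)
    return(as.integer(k_max))
  }
  as.integer(min(ok))
}

#' Call fixed-width peaks against a global Poisson background
#'
#' Windows of `peak_size` bp are anchored at each read 5' start (per
#' chromosome, and per strand when `strand_specific`); a window's count is the
#' summed weight of reads whose 5' start lies inside it. Windows at or above
#' the FDR-selected threshold are accepted greedily in descending count order
#' (ties: leftmost start, then `+` strand), rejecting windows whose start is
#' within `min_distance` of an accepted window on the same chrom/strand.
#'
#' @param reads aligned-read data.frame
#' @param cfg a [peak_call_config()]
#' @param weight_mode `"distinct_reads"` or `"all_reads"` (see
#'   [read_weights()])
#' @return data.frame of peaks (chrom, start, end, strand, clip_count,
#'   threshold_used) sorted by coordinate, with attributes `lambda`, `k_star`,
#'   `n_windows`, `peak_size`
#' @export
call_peaks <- function(reads, cfg, weight_mode = "distinct_reads") {
  stopifnot(inherits(cfg, "peak_call_config"))
  w <- read_weights(reads, weight_mode)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      clip_count = numeric(), threshold_used = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(reads) == 0) return(empty)
  L <- if (cfg$peak_size > 0) cfg$peak_size else choose_peak_size(reads)
  min_dist <- if (is.null(cfg$min_distance)) L else cfg$min_distance
  p5 <- read_five_prime(reads)
  strand_grp <- if (cfg$strand_specific) reads$strand
                else rep(".", nrow(reads))
  key <- paste(reads$chrom, strand_grp, sep = "\r")
  cand <- do.call(rbind, lapply(split(seq_len(nrow(reads)), key), function(ix) {
    ps <- p5[ix]; ws <- w[ix]
    o <- order(ps)
    ps <- ps[o]; ws <- ws[o]
    cw <- cumsum(ws)
    anchors <- unique(ps)
    hi <- findInterval(anchors + L - 1, ps)
    lo <- findInterval(anchors - 1, ps)
    counts <- cw[hi] - ifelse(lo > 0, cw[pmax(lo, 1)], 0)
    data.frame(chrom = reads$chrom[ix[1]], start = anchors,
               strand = strand_grp[ix[1]], clip_count = counts,
               stringsAsFactors = FALSE)
  }))
  rownames(cand) <- NULL
  total_w <- sum(w)
  lambda <- estimate_background_rate(total_w, L, cfg$effective_genome_size,
                                     cfg$strand_specific)
  n_windows <- ceiling((if (cfg$strand_specific) 2 else 1) *
                         cfg$effective_genome_size / L)
  tab <- tabulate(floor(cand$clip_count))
  obs_tail <- rev(cumsum(rev(tab)))
  k_star <- poisson_fdr_threshold(lambda, n_windows, obs_tail, cfg$fdr)
  cand <- cand[cand$clip_count >= k_star, , drop = FALSE]
  if (nrow(cand) == 0) {
    out <- empty
  } else {
    strand_rank <- match(cand$strand, c("+", "-", "."))
    o <- order(-cand$clip_count, cand$chrom, cand$start, strand_rank)
    cand <- cand[o, , drop = FALSE]
    gkey <- paste(cand$chrom, cand$strand, sep = "\r")
    accepted <- new.env(parent = emptyenv())
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      k <- gkey[i]
      acc <- accepted[[k]]
      if (is.null(acc) || !any(abs(acc - cand$start[i]) < min_dist)) {
        keep[i] <- TRUE
        accepted[[k]] <- c(acc, cand$start[i])
      }
    }
    cand <- cand[keep, , drop = FALSE]
    out <- data.frame(chrom = cand$chrom, start = cand$start,
                      end = cand$start + L, strand = cand$strand,
                      clip_count = cand$clip_count,
                      threshold_used = k_star, stringsAsFactors = FALSE)
    out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "lambda") <- lambda
  attr(out, "k_star") <- k_star
  attr(out, "n_windows") <- n_windows
  attr(out, "peak_size") <- L
  attr(out, "weight_mode") <- weight_mode
  out
}

#' Write called peaks as BED6 plus a sidecar TSV of calling parameters
#'
#' @param peaks output of [call_peaks()]
#' @param path BED output path; the sidecar is written to `paste0(path,
#'   ".params.tsv")`
#' @export
write_peaks <- function(peaks, path) {
  iv <- genomic_intervals(peaks$chrom, peaks$start, peaks$end,
                          name = sprintf("peak_%d", seq_len(nrow(peaks))),
                          score = peaks$clip_count, strand = peaks$strand)
  write_bed(iv, path)
  side <- c(
    paste("lambda", format(attr(peaks, "lambda"), digits = 10), sep = "\t"),
    paste("k_star", attr(peaks, "k_star"), sep = "\t"),
    paste("n_windows", attr(peaks, "n_windows"), sep = "\t"),
    paste("peak_size", attr(peaks, "peak_size"), sep = "\t"),
    paste("weight_mode", attr(peaks, "weight_mode"), sep = "\t"),
    paste("n_peaks", nrow(peaks), sep = "\t"))
  writeLines(side, paste0(path, ".params.tsv"))
  invisible(path)
}
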