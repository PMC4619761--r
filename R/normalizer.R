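# GRanges helpers ------------------------------------------------------------

intervals_to_granges <- function(df, use_strand = TRUE) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if (use_strand) ifelse(df$strand == ".", "*", df$strand) else "*")
}

# weighted read 5' starts as width-1 GRanges
reads_to_p5_granges <- function(reads, use_strand = TRUE) {
  p5 <- read_five_prime(reads)
  GenomicRanges::GRanges(
    seqnames = reads$chrom,
    ranges = IRanges::IRanges(start = p5 + 1L, width = 1L),
    strand = if (use_strand) reads$strand else "*")
}

#' Weighted read counts per transcript (5' starts within exons)
#'
#' @param reads aligned-read data.frame
#' @param transcripts a `transcript_models` object
#' @param weights per-read weights (see [read_weights()]); default 1
#' @param stranded count only reads on the transcript strand (default TRUE)
#' @return named numeric vector of counts, one per transcript (0 when none)
#' @export
count_reads_in_transcripts <- function(reads, transcripts, weights = NULL,
                                       stranded = TRUE) {
  if (is.null(weights)) weights <- rep(1, nrow(reads))
  tx_ids <- transcripts$transcripts$transcript_id
  out <- setNames(numeric(length(tx_ids)), tx_ids)
  if (!nrow(reads)) return(out)
  rg <- reads_to_p5_granges(reads, use_strand = stranded)
  eg <- intervals_to_granges(transcripts$exons, use_strand = stranded)
  hits <- GenomicRanges::findOverlaps(rg, eg, ignore.strand = !stranded)
  if (length(hits)) {
    tx_hit <- transcripts$exons$transcript_id[S4Vectors::subjectHits(hits)]
    # a read hitting several exons of one transcript must count once
    key <- paste(S4Vectors::queryHits(hits), tx_hit, sep = "\r")
    dedup <- !duplicated(key)
    sums <- rowsum(weights[S4Vectors::queryHits(hits)[dedup]], tx_hit[dedup])
    out[rownames(sums)] <- sums[, 1]
  }
  out
}

#' Compute RPKM expression records
#'
#' RPKM = 1e9 * read_count / (exonic_length * total_mapped_reads): reads per
#' kilobase of exon model per million mapped reads.
#'
#' @param counts named numeric vector of per-transcript read counts
#' @param transcripts a `transcript_models` object
#' @param total_mapped_reads total mapped reads in the library
#' @return data.frame (transcript_id, read_count, rpkm), one row per
#'   transcript in `transcripts`; uncounted transcripts get 0
#' @export
compute_rpkm <- function(counts, transcripts, total_mapped_reads) {
  if (total_mapped_reads <= 0) stop("total_mapped_reads must be > 0")
  tx <- transcripts$transcripts
  missing_model <- setdiff(names(counts), tx$transcript_id)
  if (length(missing_model)) {
    stop("no transcript model for: ", paste(missing_model, collapse = ", "))
  }
  cnt <- setNames(numeric(nrow(tx)), tx$transcript_id)
  cnt[names(counts)] <- counts
  data.frame(transcript_id = tx$transcript_id,
             read_count = unname(cnt),
             rpkm = unname(1e9 * cnt / (tx$exonic_length * total_mapped_reads)),
             stringsAsFactors = FALSE)
}

#' Assign each peak its host transcript
#'
#' The host is the transcript whose exons overlap the peak by at least 1 bp on
#' the same strand; ties go to the largest overlap, then the longest exonic
#' length, then the lexicographically smallest transcript id.
#'
#' @param peaks peak data.frame (chrom, start, end, strand)
#' @param transcripts a `transcript_models` object
#' @return character vector of transcript ids (NA where no transcript
#'   overlaps)
#' @export
assign_host_transcript <- function(peaks, transcripts) {
  n <- nrow(peaks)
  out <- rep(NA_character_, n)
  if (!n) return(out)
  pg <- intervals_to_granges(peaks)
  eg <- intervals_to_granges(transcripts$exons)
  hits <- GenomicRanges::findOverlaps(pg, eg)
  if (!length(hits)) return(out)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::pintersect(pg[qh], eg[sh])
  ow <- GenomicRanges::width(ov)
  tx_hit <- transcripts$exons$transcript_id[sh]
  # total overlap per (peak, transcript): a peak can span several exons
  agg <- rowsum(ow, paste(qh, tx_hit, sep = "\r"))
  keys <- strsplit(rownames(agg), "\r", fixed = TRUE)
  peak_i <- as.integer(vapply(keys, `[`, "", 1))
  tx_i <- vapply(keys, `[`, "", 2)
  exlen <- transcripts$transcripts$exonic_length[
    match(tx_i, transcripts$transcripts$transcript_id)]
  o <- order(peak_i, -agg[, 1], -exlen, tx_i)
  first <- !duplicated(peak_i[o])
  out[peak_i[o][first]] <- tx_i[o][first]
  out
}

#' Score and rank peaks under one normalization strategy
#'
#' Five strategies are supported, with peak CLIP count `c`, peak width `w`,
#' host transcript `t` of exonic length `L_t`, transcript-level weighted CLIP /
#' input counts `C_t` / `I_t`, weighted input count `i` in the peak window,
#' library sizes `N_c`, `N_i`, transcript RPKM `R_t`, and pseudocount `alpha`:
#'
#' * `raw`:       `c`
#' * `ave_clip`:  `c / (C_t * w / L_t + alpha)`
#' * `ave_input`: `(c / N_c) / ((I_t * w / L_t + alpha) / N_i)`
#' * `input`:     `((c + alpha) / N_c) / ((i + alpha) / N_i)`
#' * `rpkm`:      `c / (R_t + alpha)`
#'
#' Library-size scaling (`N_c`, `N_i`) can be disabled with
#' `library_scaling = FALSE`. Peaks with no host transcript are scored
#' normally under `raw`/`input` and pushed to the worst ranks (flagged) under
#' the transcript-dependent strategies. Ranks are 1..n by descending score,
#' ties broken by higher `c`, then coordinate.
#'
#' @param peaks output of [call_peaks()]
#' @param strategy one of `"raw"`, `"ave_clip"`, `"ave_input"`, `"input"`,
#'   `"rpkm"`
#' @param transcripts `transcript_models` (needed by ave_clip, ave_input,
#'   rpkm)
#' @param clip_reads CLIP aligned reads (needed by ave_clip)
#' @param input_reads input-RNA aligned reads (needed by ave_input, input)
#' @param expression RPKM data.frame from [compute_rpkm()] (needed by rpkm)
#' @param weight_mode read-usage mode for CLIP-derived counts
#' @param input_weight_mode read-usage mode for input-derived counts
#' @param alpha pseudocount on denominators (and on both counts for `input`)
#' @param library_scaling divide by library sizes in input/ave_input
#' @return data.frame of scored peaks: peak columns plus `transcript_id`,
#'   `strategy`, `score`, `rank`, `flagged`, sorted by rank
#' @export
score_peaks <- function(peaks,
                        strategy = c("raw", "ave_clip", "ave_input", "input",
                                     "rpkm"),
                        transcripts = NULL, clip_reads = NULL,
                        input_reads = NULL, expression = NULL,
                        weight_mode = "distinct_reads",
                        input_weight_mode = weight_mode,
                        alpha = 1, library_scaling = TRUE) {
  strategy <- match.arg(strategy)
  n <- nrow(peaks)
  need <- function(obj, what) {
    if (is.null(obj)) stop("strategy '", strategy, "' requires ", what)
  }
  w <- attr(peaks, "peak_size")
  if (is.null(w)) w <- if (n) peaks$end[1] - peaks$start[1] else 0L
  cc <- peaks$clip_count
  host <- rep(NA_character_, n)
  flagged <- rep(FALSE, n)
  if (strategy %in% c("ave_clip", "ave_input", "rpkm") ||
      !is.null(transcripts)) {
    if (strategy %in% c("ave_clip", "ave_input", "rpkm")) {
      need(transcripts, "transcript models")
    }
    if (!is.null(transcripts) && n) {
      host <- assign_host_transcript(peaks, transcripts)
    }
  }
  score <- switch(strategy,
    raw = cc,
    ave_clip = {
      need(clip_reads, "the CLIP read set")
      Ct <- count_reads_in_transcripts(
        clip_reads, transcripts, read_weights(clip_reads, weight_mode))
      Lt <- setNames(transcripts$transcripts$exonic_length,
                     transcripts$transcripts$transcript_id)
      dens <- Ct[host] * w / Lt[host]
      cc / (dens + alpha)
    },
    ave_input = {
      need(input_reads, "the input-RNA read set")
      Nc <- sum(read_weights_total(peaks, clip_reads, weight_mode, cc))
      Iw <- read_weights(input_reads, input_weight_mode)
      Ni <- sum(Iw)
      It <- count_reads_in_transcripts(input_reads, transcripts, Iw)
      Lt <- setNames(transcripts$transcripts$exonic_length,
                     transcripts$transcripts$transcript_id)
      dens <- It[host] * w / Lt[host]
      if (library_scaling) (cc / Nc) / ((dens + alpha) / Ni)
      else cc / (dens + alpha)
    },
    input = {
      need(input_reads, "the input-RNA read set")
      Nc <- sum(read_weights_total(peaks, clip_reads, weight_mode, cc))
      Iw <- read_weights(input_reads, input_weight_mode)
      Ni <- sum(Iw)
      i_cnt <- count_reads_in_windows(input_reads, peaks, Iw)
      if (library_scaling) ((cc + alpha) / Nc) / ((i_cnt + alpha) / Ni)
      else (cc + alpha) / (i_cnt + alpha)
    },
    rpkm = {
      need(expression, "an RPKM expression table")
      Rt <- setNames(expression$rpkm, expression$transcript_id)
      cc / (Rt[host] + alpha)
    })
  score <- unname(score)
  if (strategy %in% c("ave_clip", "ave_input", "rpkm")) {
    flagged <- is.na(host)
    score[flagged] <- NA_real_
  }
  strand_rank <- match(peaks$strand, c("+", "-", "."))
  o <- order(flagged, -ifelse(is.na(score), -Inf, score), -cc,
             peaks$chrom, peaks$start, strand_rank)
  out <- peaks[o, , drop = FALSE]
  out$transcript_id <- host[o]
  out$strategy <- strategy
  out$score <- score[o]
  out$rank <- seq_len(n)
  out$flagged <- flagged[o]
  rownames(out) <- NULL
  attr(out, "peak_size") <- w
  attr(out, "alpha") <- alpha
  attr(out, "library_scaling") <- library_scaling
  out
}

# CLIP library size: total weighted CLIP reads if the read set is supplied,
# otherwise the summed peak counts (a lower bound, used only when scaling)
read_weights_total <- function(peaks, clip_reads, weight_mode, cc) {
  if (!is.null(clip_reads)) sum(read_weights(clip_reads, weight_mode))
  else sum(cc)
}

#' Weighted read count with 5' start inside each window
#'
#' @param reads aligned-read data.frame
#' @param windows interval data.frame (e.g. peaks)
#' @param weights per-read weights; default 1
#' @param stranded count only same-strand reads when the window is stranded
#' @return numeric vector, one count per window
#' @export
count_reads_in_windows <- function(reads, windows, weights = NULL,
                                   stranded = TRUE) {
  if (is.null(weights)) weights <- rep(1, nrow(reads))
  out <- numeric(nrow(windows))
  if (!nrow(reads) || !nrow(windows)) return(out)
  rg <- reads_to_p5_granges(reads, use_strand = stranded)
  wg <- intervals_to_granges(windows, use_strand = stranded)
  hits <- GenomicRanges::findOverlaps(wg, rg, ignore.strand = !stranded)
  if (length(hits)) {
    sums <- rowsum(weights[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits))
    out[as.integer(rownames(sums))] <- sums[, 1]
  }
  out
}

#' Write a ranked peak table as TSV
#'
#' @param scored output of [score_peaks()]
#' @param path output path
#' @export
write_ranked_peaks <- function(scored, path) {
  if (nrow(scored) && anyDuplicated(scored$rank)) {
    stop("duplicate ranks in scored peak table")
  }
  df <- scored[order(scored$rank),
               c("chrom", "start", "end", "strand", "clip_count",
                 "transcript_id", "strategy", "score", "rank")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
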