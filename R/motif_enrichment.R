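#' All k-mers over the DNA alphabet, lexicographic
#' @param k k-mer length
#' @return character vector of length `4^k`
#' @export
all_kmers <- function(k) {
  stopifnot(k >= 1)
  g <- do.call(expand.grid,
               c(rep(list(c("A", "C", "G", "T")), k),
                 stringsAsFactors = FALSE))
  # vary the last position fastest -> lexicographic order
  sort(apply(g, 1, paste, collapse = ""))
}

#' Per-k-mer sequence-presence counts
#'
#' For each of the `4^k` k-mers, counts the number of sequences containing at
#' least one occurrence (presence, not total occurrences). Windows containing
#' N are skipped.
#'
#' @param seqs character vector of sequences
#' @param k k-mer length
#' @return named integer vector over all `4^k` k-mers
#' @export
kmer_presence_counts <- function(seqs, k = 4L) {
  stopifnot(k >= 1)
  kmers <- all_kmers(k)
  out <- setNames(integer(length(kmers)), kmers)
  if (length(seqs) && max(nchar(seqs)) < k) {
    warning("k = ", k, " exceeds every sequence length; all counts are zero")
    return(out)
  }
  present <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    subs <- substring(s, 1:(n - k + 1L), k:n)
    unique(subs[!grepl("[^ACGT]", subs)])
  }), use.names = FALSE)
  if (length(present)) {
    tab <- table(factor(present, levels = kmers))
    out[] <- as.integer(tab)
  }
  out
}

gc_fraction <- function(seqs) {
  n_gc <- nchar(gsub("[^GC]", "", seqs))
  n_acgt <- nchar(gsub("[^ACGT]", "", seqs))
  ifelse(n_acgt > 0, n_gc / n_acgt, NA_real_)
}

#' Sample a GC-matched genomic background set
#'
#' Samples `n_bg` regions from the genome whose lengths are drawn (with
#' replacement) from the target length distribution and whose GC-content
#' histogram over `gc_bins` equal-width bins matches the targets'
#' (proportional allocation, rejection sampling per bin). Deterministic given
#' `seed`.
#'
#' @param genome named character vector of chromosome sequences
#' @param target_seqs target sequences to match
#' @param n_bg number of background sequences (> 0)
#' @param gc_bins number of equal-width GC bins over \[0, 1\]
#' @param seed integer RNG seed (NULL leaves the RNG state alone)
#' @param max_attempts rejection-sampling attempts per sequence
#' @return a `background_set` list: `$kind`, `$sequences` (named character
#'   vector), `$provenance`
#' @export
sample_gc_matched_background <- function(genome, target_seqs, n_bg,
                                         gc_bins = 10L, seed = NULL,
                                         max_attempts = 10000L) {
  if (n_bg <= 0) stop("n_bg must be > 0 (a background set cannot be empty)")
  if (!length(target_seqs)) stop("no target sequences to match")
  if (!is.null(seed)) set.seed(seed)
  breaks <- seq(0, 1, length.out = gc_bins + 1L)
  gc_t <- gc_fraction(target_seqs)
  bin_t <- cut(gc_t, breaks, include.lowest = TRUE, labels = FALSE)
  # proportional allocation with largest-remainder rounding
  prop <- tabulate(bin_t, nbins = gc_bins) / length(bin_t)
  alloc <- floor(prop * n_bg)
  rem <- n_bg - sum(alloc)
  if (rem > 0) {
    frac <- prop * n_bg - alloc
    alloc[order(-frac)[seq_len(rem)]] <- alloc[order(-frac)[seq_len(rem)]] + 1L
  }
  lens_pool <- nchar(target_seqs)
  chrom_len <- nchar(genome)
  seqs <- character(0)
  for (b in which(alloc > 0)) {
    got <- 0L
    while (got < alloc[b]) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        len <- sample(lens_pool, 1L)
        chrom <- sample(names(genome), 1L, prob = chrom_len)
        if (chrom_len[[chrom]] < len) next
        s0 <- sample.int(chrom_len[[chrom]] - len + 1L, 1L)
        s <- substr(genome[[chrom]], s0, s0 + len - 1L)
        if (grepl("N", s, fixed = TRUE)) next
        gb <- cut(gc_fraction(s), breaks, include.lowest = TRUE,
                  labels = FALSE)
        if (!is.na(gb) && gb == b) { ok <- TRUE; break }
      }
      if (!ok) {
        stop(sprintf(
          "could not fill GC bin %d (GC in [%.2f, %.2f]) after %d attempts",
          b, breaks[b], breaks[b + 1L], max_attempts))
      }
      seqs <- c(seqs, s)
      got <- got + 1L
    }
  }
  structure(list(
    kind = "gc_matched_genomic",
    sequences = setNames(seqs, sprintf("bg_%d", seq_along(seqs))),
    provenance = list(n_bg = n_bg, gc_bins = gc_bins, seed = seed)),
    class = "background_set")
}

#' Wrap sequences as a background set
#'
#' Used for the input-peak background model (sequences of peaks called from
#' the input sample) or any user-supplied background.
#'
#' @param sequences character vector of background sequences (non-empty)
#' @param kind `"input_peaks"` or `"user_supplied"`
#' @return a `background_set`
#' @export
background_from_sequences <- function(sequences,
                                      kind = c("input_peaks",
                                               "user_supplied")) {
  kind <- match.arg(kind)
  if (!length(sequences)) stop("a background set cannot be empty")
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("bg_%d", seq_along(sequences))
  }
  structure(list(kind = kind, sequences = sequences,
                 provenance = list(n_bg = length(sequences))),
            class = "background_set")
}

#' One-sided enrichment test for k-mer presence
#'
#' One-sided Fisher's exact test (hypergeometric upper tail) for
#' over-representation of sequences containing the k-mer in the target set
#' relative to the background set.
#'
#' @param target_with,target_total sequences containing the k-mer / total, in
#'   the target set
#' @param bg_with,bg_total same for the background set
#' @return p-value in (0, 1\]
#' @export
enrichment_test <- function(target_with, target_total, bg_with, bg_total) {
  if (target_total <= 0 || bg_total <= 0) stop("set totals must be > 0")
  if (target_with > target_total || bg_with > bg_total ||
      target_with < 0 || bg_with < 0) {
    stop("counts inconsistent with totals")
  }
  phyper(target_with - 1, target_with + bg_with,
         (target_total - target_with) + (bg_total - bg_with),
         target_total, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; output order matches
#' input order.
#'
#' @param p_values numeric vector of p-values in (0, 1\]
#' @return q-values, same length and order
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric())
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Discover enriched k-mers against a background set
#'
#' Tests all `4^k` k-mers for over-representation of sequence presence in the
#' target set versus the background, adjusts across all `4^k` tests with
#' Benjamini-Hochberg, and ranks significant k-mers (q below `fdr_cut`) by
#' presence percentage, ties broken by smaller p, then lexicographic k-mer.
#'
#' @param target_seqs character vector of target (peak) sequences
#' @param background a `background_set`
#' @param k k-mer length (default 4, tetramers)
#' @param fdr_cut significance cutoff on q (default 0.001)
#' @return data.frame of class `kmer_enrichment` with one row per k-mer
#'   (kmer, target_with, target_total, bg_with, bg_total, percent, p_value,
#'   q_value, rank), significant rows first in rank order; non-significant
#'   rows have `rank = NA`
#' @export
discover_motifs <- function(target_seqs, background, k = 4L,
                            fdr_cut = 0.001) {
  stopifnot(inherits(background, "background_set"))
  if (!length(target_seqs)) stop("no target sequences")
  tc <- kmer_presence_counts(target_seqs, k)
  bc <- kmer_presence_counts(background$sequences, k)
  tt <- length(target_seqs)
  bt <- length(background$sequences)
  p <- phyper(tc - 1, tc + bc, (tt - tc) + (bt - bc), tt,
              lower.tail = FALSE)
  q <- bh_fdr(p)
  percent <- tc / tt
  df <- data.frame(kmer = names(tc), target_with = unname(tc),
                   target_total = tt, bg_with = unname(bc), bg_total = bt,
                   percent = unname(percent), p_value = unname(p),
                   q_value = unname(q), rank = NA_integer_,
                   stringsAsFactors = FALSE)
  sig <- df$q_value < fdr_cut
  if (any(sig)) {
    o <- order(-df$percent[sig], df$p_value[sig], df$kmer[sig])
    df$rank[which(sig)[o]] <- seq_len(sum(sig))
  }
  df <- df[order(is.na(df$rank), df$rank, -df$percent, df$kmer), ,
           drop = FALSE]
  rownames(df) <- NULL
  attr(df, "background_kind") <- background$kind
  attr(df, "fdr_cut") <- fdr_cut
  class(df) <- c("kmer_enrichment", "data.frame")
  df
}

#' @export
print.kmer_enrichment <- function(x, top = 10L, ...) {
  cat(sprintf("k-mer enrichment vs %s background (%d significant at q < %g)\n",
              attr(x, "background_kind"), sum(!is.na(x$rank)),
              attr(x, "fdr_cut")))
  print.data.frame(utils::head(as.data.frame(x), top), digits = 4)
  invisible(x)
}

#' Write a k-mer enrichment table as TSV
#' @param stats a `kmer_enrichment` data.frame
#' @param path output path
#' @export
write_motif_table <- function(stats, path) {
  df <- as.data.frame(stats)
  df$background_kind <- attr(stats, "background_kind")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
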