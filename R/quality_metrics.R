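# take the first top_n peaks by rank (or given order when unranked)
top_peaks <- function(peaks, top_n) {
  if (top_n < 1) stop("top_n must be >= 1")
  if (!is.null(peaks$rank)) peaks <- peaks[order(peaks$rank), , drop = FALSE]
  utils::head(peaks, top_n)
}

#' Fraction of top-ranked peaks overlapping exons
#'
#' A peak counts as exonic when it overlaps any exon by at least 1 bp
#' (half-open intervals `[a,b)`, `[c,d)` overlap iff `a < d && c < b`);
#' strand-agnostic by default, matching common BEDTools usage.
#'
#' @param peaks ranked peak data.frame
#' @param exons interval data.frame of exons
#' @param top_n number of top peaks to assess
#' @param stranded require same-strand overlap
#' @return fraction in \[0, 1\]
#' @export
exonic_fraction <- function(peaks, exons, top_n = nrow(peaks),
                            stranded = FALSE) {
  pk <- top_peaks(peaks, top_n)
  if (!nrow(pk)) return(NaN)
  if (!nrow(exons)) return(0)
  pg <- intervals_to_granges(pk, use_strand = stranded)
  eg <- intervals_to_granges(exons, use_strand = stranded)
  hit <- GenomicRanges::countOverlaps(pg, eg, ignore.strand = !stranded) > 0
  mean(hit)
}

#' Fraction of top-ranked peaks containing a motif
#'
#' The peak sequence is extracted strand-aware; the motif must occur exactly
#' at least once.
#'
#' @param peaks ranked peak data.frame
#' @param genome named character vector of chromosome sequences
#' @param motif DNA motif over A,C,G,T (default "GGAG", the Lin28 core motif)
#' @param top_n number of top peaks to assess
#' @return fraction in \[0, 1\]
#' @export
motif_fraction <- function(peaks, genome, motif = "GGAG",
                           top_n = nrow(peaks)) {
  if (!grepl("^[ACGT]+$", motif)) {
    stop("motif must be a non-empty string over A,C,G,T")
  }
  pk <- top_peaks(peaks, top_n)
  if (!nrow(pk)) return(NaN)
  seqs <- extract_sequence(genome, pk)
  mean(grepl(motif, seqs, fixed = TRUE))
}

#' Peak-quality curves over a top-N grid
#'
#' Evaluates exonic fraction and motif fraction for each ranking strategy at
#' each grid point.
#'
#' @param scored_by_strategy named list of scored peak data.frames (one per
#'   strategy; see [score_peaks()])
#' @param exons interval data.frame of exons
#' @param genome named character vector of chromosome sequences
#' @param grid ascending integer vector of top-N values (e.g.
#'   `c(100, 200, 500, 1000, 3000)`)
#' @param motif DNA motif for [motif_fraction()]
#' @return data.frame (strategy, top_n, exonic_fraction, motif_fraction)
#' @export
quality_curves <- function(scored_by_strategy, exons, genome,
                           grid = c(100, 200, 500, 1000, 3000),
                           motif = "GGAG") {
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly ascending")
  }
  rows <- lapply(names(scored_by_strategy), function(st) {
    pk <- scored_by_strategy[[st]]
    data.frame(
      strategy = st,
      top_n = as.integer(grid),
      exonic_fraction = vapply(grid, function(n)
        exonic_fraction(pk, exons, top_n = n), 0),
      motif_fraction = vapply(grid, function(n)
        motif_fraction(pk, genome, motif = motif, top_n = n), 0),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Precision of top-ranked peaks against planted binding sites
#'
#' @param peaks ranked peak data.frame
#' @param sites interval data.frame of true binding sites
#' @param top_n number of top peaks to assess
#' @param stranded require same-strand overlap (default TRUE)
#' @return fraction of top peaks overlapping a site by >= 1 bp
#' @export
site_precision <- function(peaks, sites, top_n = nrow(peaks),
                           stranded = TRUE) {
  pk <- top_peaks(peaks, top_n)
  if (!nrow(pk)) return(NaN)
  if (!nrow(sites)) return(0)
  pg <- intervals_to_granges(pk, use_strand = stranded)
  sg <- intervals_to_granges(sites, use_strand = stranded)
  mean(GenomicRanges::countOverlaps(pg, sg, ignore.strand = !stranded) > 0)
}

#' Cross-sample rank correlation of shared targets
#'
#' Pairs targets between two scored peak lists (by an explicit key pairing,
#' e.g. shared gene ids or an ortholog table), takes each target's best score
#' in each list, and correlates them.
#'
#' @param scored_a,scored_b scored peak data.frames carrying a key column
#' @param pairing data.frame with columns `key_a`, `key_b`; NULL pairs
#'   identical keys present in both lists
#' @param method `"spearman"` (default; the lists are rankings) or
#'   `"pearson"`
#' @param key name of the key column (default `"transcript_id"`)
#' @return correlation coefficient in \[-1, 1\]
#' @export
cross_species_rank_correlation <- function(scored_a, scored_b, pairing = NULL,
                                           method = c("spearman", "pearson"),
                                           key = "transcript_id") {
  method <- match.arg(method)
  best <- function(df) {
    df <- df[!is.na(df[[key]]) & !is.na(df$score), , drop = FALSE]
    if (!nrow(df)) return(setNames(numeric(), character()))
    tapply(df$score, df[[key]], max)
  }
  ba <- best(scored_a); bb <- best(scored_b)
  if (is.null(pairing)) {
    shared <- intersect(names(ba), names(bb))
    pairing <- data.frame(key_a = shared, key_b = shared,
                          stringsAsFactors = FALSE)
  }
  keep <- pairing$key_a %in% names(ba) & pairing$key_b %in% names(bb)
  pairing <- pairing[keep, , drop = FALSE]
  if (nrow(pairing) < 3) {
    stop("need at least 3 paired targets present in both lists")
  }
  cor(unname(ba[pairing$key_a]), unname(bb[pairing$key_b]), method = method)
}
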