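#' Collapse PCR duplicates
#'
#' Reads mapping to the same location are collapsed to one representative
#' carrying the group size in `copy_count`. The duplicate key is either the
#' full span `(chrom, start, end, strand)` or the 5' position
#' `(chrom, 5'-coordinate, strand)`; with fixed-length reads the two coincide.
#'
#' @param reads aligned-read data.frame, all `copy_count == 1`
#' @param key `"full_span"` (default) or `"five_prime"`
#' @return list with `$reads` (collapsed, sorted by chrom, start, end, strand)
#'   and `$report` (a `dup_report`: totals, duplication rate, copy-count
#'   histogram)
#' @export
collapse_duplicates <- function(reads, key = c("full_span", "five_prime")) {
  key <- match.arg(key)
  if (nrow(reads) && any(reads$copy_count != 1L)) {
    stop("reads already collapsed (copy_count > 1); refusing to collapse twice")
  }
  if (nrow(reads) == 0) {
    rep0 <- structure(list(total_reads = 0L, distinct_reads = 0L,
                           duplication_rate = 0,
                           copy_count_histogram = integer()),
                      class = "dup_report")
    return(list(reads = reads, report = rep0))
  }
  if (key == "full_span") {
    o <- order(reads$chrom, reads$start, reads$end, reads$strand)
    r <- reads[o, , drop = FALSE]
    new_grp <- c(TRUE, r$chrom[-1] != r$chrom[-nrow(r)] |
                   r$start[-1] != r$start[-nrow(r)] |
                   r$end[-1] != r$end[-nrow(r)] |
                   r$strand[-1] != r$strand[-nrow(r)])
  } else {
    p5 <- read_five_prime(reads)
    o <- order(reads$chrom, p5, reads$strand, reads$start, reads$end)
    r <- reads[o, , drop = FALSE]
    p5 <- p5[o]
    new_grp <- c(TRUE, r$chrom[-1] != r$chrom[-nrow(r)] |
                   p5[-1] != p5[-nrow(r)] |
                   r$strand[-1] != r$strand[-nrow(r)])
  }
  grp <- cumsum(new_grp)
  sizes <- tabulate(grp)
  rep_idx <- which(new_grp)  # first (leftmost/shortest) member of each group
  out <- r[rep_idx, , drop = FALSE]
  out$copy_count <- as.integer(sizes)
  o2 <- order(out$chrom, out$start, out$end, out$strand)
  out <- out[o2, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("aligned_reads", "data.frame")
  total <- nrow(reads); distinct <- nrow(out)
  hist <- table(out$copy_count)
  report <- structure(list(
    total_reads = total,
    distinct_reads = distinct,
    duplication_rate = 1 - distinct / total,
    copy_count_histogram = setNames(as.integer(hist), names(hist))
  ), class = "dup_report")
  list(reads = out, report = report)
}

#' @export
print.dup_report <- function(x, ...) {
  cat(sprintf("duplication report: %d total, %d distinct (rate %.3f)\n",
              x$total_reads, x$distinct_reads, x$duplication_rate))
  if (length(x$copy_count_histogram)) {
    cat("copy-count histogram (copies: frequency):\n")
    h <- x$copy_count_histogram
    cat(paste(sprintf("  %s: %d", names(h), h), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Write a duplication report as TSV
#' @param report a `dup_report`
#' @param path output path
#' @export
write_dup_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("total_reads", report$total_reads, sep = "\t"),
    paste("distinct_reads", report$distinct_reads, sep = "\t"),
    paste("duplication_rate", format(report$duplication_rate, digits = 10),
          sep = "\t")), con)
  h <- report$copy_count_histogram
  if (length(h)) {
    writeLines(paste(paste0("copies_", names(h)), h, sep = "\t"), con)
  }
  invisible(path)
}

#' Per-read counting weights for a read-usage mode
#'
#' Implements the all-reads vs distinct-reads comparison arm: in
#' `"all_reads"` mode each collapsed read contributes its `copy_count` to
#' downstream window counts; in `"distinct_reads"` mode every read counts 1.
#'
#' @param reads aligned-read data.frame (typically collapsed)
#' @param mode `"all_reads"` or `"distinct_reads"`
#' @return numeric weight vector, one per read
#' @export
read_weights <- function(reads, mode = c("distinct_reads", "all_reads")) {
  if (length(mode) == 1 && !mode %in% c("distinct_reads", "all_reads")) {
    stop("unknown read mode: ", mode)
  }
  mode <- match.arg(mode)
  if (mode == "all_reads") as.numeric(reads$copy_count)
  else rep(1, nrow(reads))
}
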