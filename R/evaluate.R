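#' Run the full factorial evaluation (read modes x ranking strategies)
#'
#' Collapses PCR duplicates, calls peaks once per read mode at the configured
#' FDR, scores the peaks under every requested strategy, and computes
#' exonic-fraction / motif-fraction quality curves on a top-N grid — the full
#' comparison design: duplicate handling crossed with normalization strategy.
#'
#' @param sim a `clip_simulation` from [simulate_clip_experiment()] (or a
#'   compatible list with genome, transcripts, clip_reads, input_reads,
#'   rnaseq_reads)
#' @param strategies ranking strategies to evaluate
#' @param read_modes read-usage modes to evaluate
#' @param fdr peak-calling FDR
#' @param grid ascending top-N grid for quality curves
#' @param motif quality-metric motif
#' @param alpha pseudocount passed to [score_peaks()]
#' @param outdir optional directory; when given, every per-cell artifact
#'   (ranked peaks, curves, dedup report, JSON summary) is written there
#' @return an `evaluation_report` list: `$peaks` (per mode), `$scored`
#'   (per mode and strategy), `$curves` (one data.frame), `$dedup_report`,
#'   `$expression`, `$config`
#' @export
run_evaluation <- function(sim,
                           strategies = c("raw", "ave_clip", "ave_input",
                                          "input", "rpkm"),
                           read_modes = c("all_reads", "distinct_reads"),
                           fdr = 0.001,
                           grid = c(100L, 200L, 500L, 1000L, 3000L),
                           motif = "GGAG",
                           alpha = 1,
                           outdir = NULL) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  read_modes <- match.arg(read_modes, several.ok = TRUE,
                          choices = c("all_reads", "distinct_reads"))
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be ascending")
  # validate context before any compute
  if (any(strategies %in% c("ave_input", "input")) &&
      is.null(sim$input_reads)) {
    stop("strategies ave_input/input require an input-RNA read set")
  }
  if ("rpkm" %in% strategies && is.null(sim$rnaseq_reads)) {
    stop("strategy rpkm requires an RNAseq read set")
  }
  genome_size <- sum(nchar(sim$genome))
  clip <- collapse_duplicates(sim$clip_reads)
  input <- if (!is.null(sim$input_reads)) {
    collapse_duplicates(sim$input_reads)$reads
  }
  expression <- NULL
  if ("rpkm" %in% strategies) {
    rn <- sim$rnaseq_reads
    counts <- count_reads_in_transcripts(rn, sim$transcripts)
    expression <- compute_rpkm(counts, sim$transcripts, nrow(rn))
  }
  cfg <- peak_call_config(effective_genome_size = genome_size, fdr = fdr)
  peaks <- list(); scored <- list(); curve_rows <- list()
  for (mode in read_modes) {
    pk <- call_peaks(clip$reads, cfg, weight_mode = mode)
    peaks[[mode]] <- pk
    by_strategy <- list()
    for (st in strategies) {
      sc <- score_peaks(pk, st, transcripts = sim$transcripts,
                        clip_reads = clip$reads, input_reads = input,
                        expression = expression, weight_mode = mode,
                        input_weight_mode = "distinct_reads", alpha = alpha)
      by_strategy[[st]] <- sc
    }
    scored[[mode]] <- by_strategy
    cv <- quality_curves(by_strategy, sim$transcripts$exons, sim$genome,
                         grid = grid[grid <= max(1, nrow(pk))] , motif = motif)
    if (!is.null(cv) && nrow(cv)) {
      cv$read_mode <- mode
      curve_rows[[mode]] <- cv
    }
  }
  curves <- do.call(rbind, curve_rows)
  rownames(curves) <- NULL
  report <- structure(list(
    peaks = peaks, scored = scored, curves = curves,
    dedup_report = clip$report, expression = expression,
    config = list(strategies = strategies, read_modes = read_modes,
                  fdr = fdr, grid = grid, motif = motif, alpha = alpha,
                  effective_genome_size = genome_size),
    version = as.character(utils::packageVersion("clipbench"))),
    class = "evaluation_report")
  if (!is.null(outdir)) write_evaluation_report(report, outdir)
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("CLIP evaluation report\n")
  for (mode in names(x$peaks)) {
    cat(sprintf("  %s: %d peaks (k* = %d, lambda = %.3g)\n", mode,
                nrow(x$peaks[[mode]]), attr(x$peaks[[mode]], "k_star"),
                attr(x$peaks[[mode]], "lambda")))
  }
  cat(sprintf("  strategies: %s\n",
              paste(x$config$strategies, collapse = ", ")))
  invisible(x)
}

#' Write an evaluation report to disk (TSVs + JSON summary)
#'
#' @param report an `evaluation_report`
#' @param outdir output directory
#' @export
write_evaluation_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(outdir, x)
  files <- character()
  for (mode in names(report$peaks)) {
    f <- fp(sprintf("peaks_%s.bed", mode))
    write_peaks(report$peaks[[mode]], f)
    files <- c(files, f)
    for (st in names(report$scored[[mode]])) {
      f <- fp(sprintf("ranked_%s_%s.tsv", mode, st))
      write_ranked_peaks(report$scored[[mode]][[st]], f)
      files <- c(files, f)
    }
  }
  write.table(report$curves, fp("quality_curves.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_dup_report(report$dedup_report, fp("dedup_report.tsv"))
  if (!is.null(report$expression)) {
    write.table(report$expression, fp("expression.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  summary <- list(
    version = report$version,
    config = report$config,
    peak_counts = lapply(report$peaks, nrow),
    k_star = lapply(report$peaks, attr, "k_star"),
    lambda = lapply(report$peaks, attr, "lambda"),
    dedup = report$dedup_report[c("total_reads", "distinct_reads",
                                  "duplication_rate")],
    files = basename(c(files, fp("quality_curves.tsv"),
                       fp("dedup_report.tsv"))))
  jsonlite::write_json(summary, fp("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Compare read modes (distinct vs all reads)
#'
#' Summarizes the effect of duplicate collapsing: per strategy and grid
#' point, the change (distinct - all) in exonic fraction and motif fraction,
#' plus the change in total peak count.
#'
#' @param report an `evaluation_report` containing both read modes
#' @return data.frame (strategy, top_n, delta_exonic_fraction,
#'   delta_motif_fraction, delta_peak_count)
#' @export
compare_read_modes <- function(report) {
  cv <- report$curves
  if (is.null(cv) || !all(c("all_reads", "distinct_reads") %in%
                          cv$read_mode)) {
    stop("report must contain both read modes")
  }
  a <- cv[cv$read_mode == "all_reads", ]
  d <- cv[cv$read_mode == "distinct_reads", ]
  m <- merge(d, a, by = c("strategy", "top_n"),
             suffixes = c("_distinct", "_all"))
  dpk <- nrow(report$peaks$distinct_reads) - nrow(report$peaks$all_reads)
  out <- data.frame(
    strategy = m$strategy, top_n = m$top_n,
    delta_exonic_fraction =
      m$exonic_fraction_distinct - m$exonic_fraction_all,
    delta_motif_fraction = m$motif_fraction_distinct - m$motif_fraction_all,
    delta_peak_count = dpk, stringsAsFactors = FALSE)
  out[order(out$strategy, out$top_n), ]
}
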