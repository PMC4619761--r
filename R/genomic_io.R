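#' Construct a table of genomic intervals
#'
#' Intervals are plain data.frames with columns `chrom`, `start`, `end`,
#' `name`, `score`, `strand`, using 0-based half-open coordinates and strand
#' in `+`, `-` or `.` (unstranded).
#'
#' @param chrom chromosome names (non-empty strings)
#' @param start,end integer coordinates, `0 <= start < end`
#' @param name optional feature names
#' @param score optional numeric scores
#' @param strand strand characters, one of `+`, `-`, `.`
#' @return a data.frame of intervals
#' @export
genomic_intervals <- function(chrom, start, end, name = ".", score = 0,
                              strand = ".") {
  n <- length(chrom)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$start) | is.na(df$end))) {
    stop("interval coordinates must be integers")
  }
  bad <- which(df$start < 0 | df$start >= df$end)
  if (length(bad)) {
    stop(sprintf("invalid interval (need 0 <= start < end) at row %d: %s:%d-%d",
                 bad[1], df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]]))
  }
  if (any(!nzchar(df$chrom) | is.na(df$chrom))) stop("chrom must be non-empty")
  if (any(!df$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  invisible(df)
}

#' Read a BED file (3-6 columns)
#'
#' @param path path to a tab-separated BED file
#' @return interval data.frame in file order; strand is `.` when column 6 is
#'   absent
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(genomic_intervals(character(), integer(), integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3) stop(sprintf("line %d: fewer than 3 columns", i))
    s <- suppressWarnings(as.integer(f[2]))
    e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e)) {
      stop(sprintf("line %d: non-integer coordinate", i))
    }
    if (s < 0 || s >= e) {
      stop(sprintf("line %d: invalid interval %s:%s-%s", i, f[1], f[2], f[3]))
    }
  }
  get <- function(k, default) {
    vapply(fields, function(f) if (length(f) >= k) f[k] else default, "")
  }
  genomic_intervals(
    chrom = get(1, "."),
    start = as.integer(get(2, "0")),
    end = as.integer(get(3, "1")),
    name = get(4, "."),
    score = suppressWarnings(as.numeric(get(5, "0"))),
    strand = {
      st <- get(6, ".")
      st[!st %in% c("+", "-")] <- "."
      st
    }
  )
}

#' Write intervals as 6-column BED
#'
#' @param intervals interval data.frame (see [genomic_intervals()])
#' @param path output path
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  df <- intervals[, c("chrom", "start", "end", "name", "score", "strand")]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased; the record key is the header token before the
#' first whitespace. Duplicate headers are an error.
#'
#' @param path path to a FASTA file
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(setNames(character(), character()))
  ss <- Biostrings::readBStringSet(path)
  keys <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(keys)) {
    stop("duplicate FASTA headers: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  setNames(toupper(as.character(ss)), keys)
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector
#' @param path output path
#' @param width line-wrap width
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    starts <- seq(1L, max(n, 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Reverse-complement DNA strings
#'
#' @param x character vector over A,C,G,T,N (case-insensitive)
#' @return reverse complements, uppercase
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTNacgtn", "TGCANTGCAN", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Extract the strand-aware sequence of intervals from a genome
#'
#' Returns the substring `[start, end)` of the chromosome, reverse-complemented
#' for minus-strand intervals; strand `.` is treated as `+`.
#'
#' @param genome named character vector of chromosome sequences (see
#'   [read_fasta()])
#' @param intervals interval data.frame
#' @return character vector of sequences, one per interval
#' @export
extract_sequence <- function(genome, intervals) {
  validate_intervals(intervals)
  if (nrow(intervals) == 0) return(character())
  miss <- setdiff(unique(intervals$chrom), names(genome))
  if (length(miss)) stop("chromosome(s) not in genome: ",
                         paste(miss, collapse = ", "))
  lens <- nchar(genome)[intervals$chrom]
  bad <- which(intervals$end > lens)
  if (length(bad)) {
    b <- bad[1]
    stop(sprintf("interval out of bounds: %s:%d-%d(%s) on %d-bp chromosome",
                 intervals$chrom[b], intervals$start[b], intervals$end[b],
                 intervals$strand[b], lens[b]))
  }
  out <- substring(genome[intervals$chrom], intervals$start + 1L,
                   intervals$end)
  neg <- intervals$strand == "-"
  if (any(neg)) out[neg] <- reverse_complement(out[neg])
  unname(out)
}

#' Build a transcript-model set from exon tables
#'
#' A transcript-model set is a list with two data.frames: `$transcripts`
#' (transcript_id, gene_id, chrom, strand, exonic_length) and `$exons`
#' (chrom, start, end, strand, transcript_id, gene_id), exons sorted by start
#' within each transcript, book-ended/duplicate exons merged.
#'
#' @param exons data.frame with columns chrom, start, end, strand,
#'   transcript_id, gene_id (0-based half-open coordinates)
#' @return an object of class `transcript_models`
#' @export
transcript_models <- function(exons) {
  stopifnot(all(c("chrom", "start", "end", "strand",
                  "transcript_id", "gene_id") %in% names(exons)))
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$start < 0 | exons$start >= exons$end)) {
    stop("invalid exon coordinates")
  }
  if (any(!exons$strand %in% c("+", "-"))) {
    stop("transcript exons must be stranded (+ or -)")
  }
  merged <- lapply(split(exons, exons$transcript_id), function(ex) {
    if (length(unique(ex$chrom)) > 1L || length(unique(ex$strand)) > 1L) {
      stop("transcript ", ex$transcript_id[1],
           ": exons on mismatched chrom/strand")
    }
    if (length(unique(ex$gene_id)) > 1L) {
      stop("transcript ", ex$transcript_id[1], ": multiple gene_ids")
    }
    ex <- ex[order(ex$start, ex$end), , drop = FALSE]
    keep_s <- ex$start[1]
    out_s <- integer(0); out_e <- integer(0)
    cur_s <- ex$start[1]; cur_e <- ex$end[1]
    if (nrow(ex) > 1) {
      for (i in 2:nrow(ex)) {
        if (ex$start[i] <= cur_e) {  # book-ended or duplicate/overlapping
          cur_e <- max(cur_e, ex$end[i])
        } else {
          out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
          cur_s <- ex$start[i]; cur_e <- ex$end[i]
        }
      }
    }
    out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
    data.frame(chrom = ex$chrom[1], start = out_s, end = out_e,
               strand = ex$strand[1], transcript_id = ex$transcript_id[1],
               gene_id = ex$gene_id[1], stringsAsFactors = FALSE)
  })
  ex_all <- do.call(rbind, merged)
  rownames(ex_all) <- NULL
  lens <- vapply(merged, function(m) sum(m$end - m$start), 0)
  tx <- data.frame(
    transcript_id = vapply(merged, function(m) m$transcript_id[1], ""),
    gene_id = vapply(merged, function(m) m$gene_id[1], ""),
    chrom = vapply(merged, function(m) m$chrom[1], ""),
    strand = vapply(merged, function(m) m$strand[1], ""),
    exonic_length = as.integer(lens),
    stringsAsFactors = FALSE
  )
  rownames(tx) <- NULL
  structure(list(transcripts = tx, exons = ex_all),
            class = "transcript_models")
}

#' @export
print.transcript_models <- function(x, ...) {
  cat(sprintf("transcript_models: %d transcripts, %d exons\n",
              nrow(x$transcripts), nrow(x$exons)))
  invisible(x)
}

#' Read transcript models from a GTF exon subset or BED12 file
#'
#' The GTF dialect uses only `exon` feature lines and the `transcript_id` /
#' `gene_id` attributes; 1-based inclusive GTF coordinates are converted to
#' 0-based half-open. The BED12 dialect uses the block fields; the record name
#' serves as both transcript and gene id.
#'
#' @param path annotation file path
#' @param dialect `"gtf_exon_subset"` or `"bed12"`
#' @return a `transcript_models` object
#' @export
read_transcripts <- function(path, dialect = c("gtf_exon_subset", "bed12")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (dialect == "gtf_exon_subset") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    fields <- fields[vapply(fields, function(f) length(f) >= 9 &&
                              f[3] == "exon", TRUE)]
    if (!length(fields)) stop("no exon lines in GTF: ", path)
    attr_of <- function(a, key) {
      m <- regmatches(a, regexpr(paste0(key, ' "[^"]+"'), a))
      if (!length(m)) stop("GTF attribute missing: ", key)
      sub('.* "', "", sub('"$', "", m))
    }
    exons <- data.frame(
      chrom = vapply(fields, `[`, "", 1),
      start = vapply(fields, function(f) as.integer(f[4]), 0L) - 1L,
      end = vapply(fields, function(f) as.integer(f[5]), 0L),
      strand = vapply(fields, `[`, "", 7),
      transcript_id = vapply(fields, function(f) attr_of(f[9], "transcript_id"), ""),
      gene_id = vapply(fields, function(f) attr_of(f[9], "gene_id"), ""),
      stringsAsFactors = FALSE
    )
    transcript_models(exons)
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    exl <- lapply(fields, function(f) {
      if (length(f) < 12) stop("BED12 record with fewer than 12 columns")
      chrom <- f[1]; start <- as.integer(f[2]); name <- f[4]
      strand <- f[6]
      sizes <- as.integer(strsplit(sub(",$", "", f[11]), ",")[[1]])
      offs <- as.integer(strsplit(sub(",$", "", f[12]), ",")[[1]])
      data.frame(chrom = chrom, start = start + offs,
                 end = start + offs + sizes, strand = strand,
                 transcript_id = name, gene_id = name,
                 stringsAsFactors = FALSE)
    })
    transcript_models(do.call(rbind, exl))
  }
}

#' Write transcript models as GTF exon lines
#' @param tx a `transcript_models` object
#' @param path output path
#' @export
write_gtf <- function(tx, path) {
  ex <- tx$exons
  lines <- sprintf(
    '%s\tclipbench\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    ex$chrom, ex$start + 1L, ex$end, ex$strand, ex$gene_id, ex$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Write transcript models as BED12
#' @param tx a `transcript_models` object
#' @param path output path
#' @export
write_bed12 <- function(tx, path) {
  rows <- vapply(split(tx$exons, tx$exons$transcript_id), function(ex) {
    ex <- ex[order(ex$start), , drop = FALSE]
    s <- min(ex$start); e <- max(ex$end)
    paste(ex$chrom[1], s, e, ex$transcript_id[1], 0, ex$strand[1], s, e,
          "0", nrow(ex),
          paste0(paste(ex$end - ex$start, collapse = ","), ","),
          paste0(paste(ex$start - s, collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(unname(rows), path)
  invisible(path)
}

#' Read aligned reads from BED6
#'
#' Each BED record becomes one aligned read with `copy_count = 1`. Reads must
#' be stranded.
#'
#' @param path BED file path
#' @return aligned-read data.frame (chrom, start, end, strand, copy_count)
#' @export
read_aligned_bed <- function(path) {
  iv <- read_bed(path)
  if (nrow(iv) && any(iv$strand == ".")) {
    stop("aligned reads must have strand (+/-) in BED column 6")
  }
  aligned_reads(iv$chrom, iv$start, iv$end, iv$strand)
}

#' Construct an aligned-read table
#'
#' @param chrom,start,end,strand interval fields (strand `+` or `-`)
#' @param copy_count amplification copy counts (1 on ingestion)
#' @return data.frame with class `aligned_reads`
#' @export
aligned_reads <- function(chrom, start, end, strand, copy_count = 1L) {
  n <- max(length(chrom), length(start), length(end), length(strand))
  if (length(start) == 0L) n <- 0L
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = rep_len(as.integer(start), n),
                   end = rep_len(as.integer(end), n),
                   strand = rep_len(as.character(strand), n),
                   copy_count = rep_len(as.integer(copy_count), n),
                   stringsAsFactors = FALSE)
  if (n) {
    if (any(df$start < 0 | df$start >= df$end)) stop("invalid read interval")
    if (any(!df$strand %in% c("+", "-"))) stop("reads must be on + or - strand")
    if (any(df$copy_count < 1L)) stop("copy_count must be >= 1")
  }
  class(df) <- c("aligned_reads", "data.frame")
  df
}

#' Read a minimal SAM subset into aligned reads
#'
#' Uses only RNAME, 1-based POS, the FLAG strand bit and the CIGAR-derived
#' reference span. Header lines and unmapped records are skipped.
#'
#' @param path SAM file path
#' @return aligned-read data.frame
#' @export
read_sam_reads <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  keep_chrom <- character(); keep_s <- integer(); keep_e <- integer()
  keep_strand <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) stop(sprintf("SAM line %d: fewer than 11 fields", i))
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L) next  # unmapped
    span <- cigar_reference_span(f[6])
    if (span == 0L) next
    pos <- as.integer(f[4]) - 1L
    keep_chrom <- c(keep_chrom, f[3])
    keep_s <- c(keep_s, pos)
    keep_e <- c(keep_e, pos + span)
    keep_strand <- c(keep_strand, if (bitwAnd(flag, 16L)) "-" else "+")
  }
  aligned_reads(keep_chrom, keep_s, keep_e, keep_strand)
}

# reference span consumed by a CIGAR string (M, D, N, =, X consume reference)
cigar_reference_span <- function(cigar) {
  if (cigar == "*") return(0L)
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[MIDNSHP=X]", "", ops))
  kind <- sub("\\d+", "", ops)
  sum(lens[kind %in% c("M", "D", "N", "=", "X")])
}

# 0-based genomic coordinate of the 5' (crosslink-proximal) base of each read
read_five_prime <- function(reads) {
  ifelse(reads$strand == "+", reads$start, reads$end - 1L)
}
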