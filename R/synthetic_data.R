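#' Simulation configuration for a synthetic CLIP experiment
#'
#' The generator emulates the statistical structure a CLIP-Seq benchmark
#' needs: transcripts with exon/intron structure on a random genome,
#' log-normal transcript abundance, planted exonic binding sites carrying a
#' motif core with log-normal affinities, CLIP reads drawn as a
#' signal/background mixture (signal proportional to affinity x abundance,
#' background proportional to abundance with an intronic component and shared
#' fragmentation hotspots), PCR duplication with geometric copy counts,
#' input-RNA reads tracking abundance plus fragmentation bias, RNAseq reads
#' uniform over exons, and compositional confounder k-mers seeded into coding
#' sequence.
#'
#' @param seed integer RNG seed
#' @param n_transcripts number of transcripts (one gene each)
#' @param exons_per_transcript integer range `c(min, max)`
#' @param exon_length,intron_length bp ranges `c(min, max)`
#' @param intergenic_gap bp between transcripts
#' @param abundance_meanlog,abundance_sdlog log-normal abundance model
#' @param n_true_sites number of planted binding sites
#' @param affinity_meanlog,affinity_sdlog log-normal affinity model
#' @param motif motif written at each site (default "GGAG")
#' @param signal_fraction fraction of CLIP fragments drawn from true sites
#' @param clip_fragments number of unique CLIP fragments (pre-amplification)
#' @param input_reads,rnaseq_reads control library sizes
#' @param read_length maximum read length in bp (the sequenced length)
#' @param read_length_min minimum mapped-read length in bp (adapter-trimmed
#'   fragments shorter than the read are trimmed to fragment length; the
#'   shortest alignable length is 18 nt)
#' @param duplication_mean mean PCR copy count (geometric; 1 = none)
#' @param intronic_background_fraction fraction of CLIP background fragments
#'   placed in introns
#' @param input_intronic_fraction fraction of input-RNA fragments placed in
#'   introns (rRNA-depleted total RNA is dominated by unspliced pre-mRNA, so
#'   input carries substantially more intronic sequence than the CLIP
#'   background of an mRNA-binding protein)
#' @param fragmentation_bias_shape Gamma shape of per-bin fragmentation
#'   hotspot weights shared by CLIP background and input (smaller = stronger
#'   hotspots; `Inf` disables the bias)
#' @param fragmentation_bin hotspot bin width in bp
#' @param positional_jitter max |offset| of a signal read 5' start from the
#'   site center
#' @param confounder_kmers named numeric vector: excess occurrence factor per
#'   confounder k-mer seeded into exonic sequence
#' @return a `clip_sim_config` list
#' @export
clip_sim_config <- function(seed = 17L,
                            n_transcripts = 200L,
                            exons_per_transcript = c(2L, 4L),
                            exon_length = c(150L, 400L),
                            intron_length = c(1000L, 5000L),
                            intergenic_gap = 20000L,
                            abundance_meanlog = 0,
                            abundance_sdlog = 1.5,
                            n_true_sites = 500L,
                            affinity_meanlog = 0,
                            affinity_sdlog = 1,
                            motif = "GGAG",
                            signal_fraction = 0.3,
                            clip_fragments = 1e5,
                            input_reads = 1e5,
                            rnaseq_reads = 1e5,
                            read_length = 36L,
                            read_length_min = 18L,
                            duplication_mean = 3,
                            intronic_background_fraction = 0.2,
                            input_intronic_fraction = 0.5,
                            fragmentation_bias_shape = 0.5,
                            fragmentation_bin = 50L,
                            positional_jitter = 15L,
                            confounder_kmers = c(CTGG = 3, GCTG = 3,
                                                 CCTG = 3)) {
  cfg <- list(seed = as.integer(seed), n_transcripts = as.integer(n_transcripts),
              exons_per_transcript = as.integer(exons_per_transcript),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              intergenic_gap = as.integer(intergenic_gap),
              abundance_meanlog = abundance_meanlog,
              abundance_sdlog = abundance_sdlog,
              n_true_sites = as.integer(n_true_sites),
              affinity_meanlog = affinity_meanlog,
              affinity_sdlog = affinity_sdlog,
              motif = motif,
              signal_fraction = signal_fraction,
              clip_fragments = as.integer(clip_fragments),
              input_reads = as.integer(input_reads),
              rnaseq_reads = as.integer(rnaseq_reads),
              read_length = as.integer(read_length),
              read_length_min = as.integer(read_length_min),
              duplication_mean = duplication_mean,
              intronic_background_fraction = intronic_background_fraction,
              input_intronic_fraction = input_intronic_fraction,
              fragmentation_bias_shape = fragmentation_bias_shape,
              fragmentation_bin = as.integer(fragmentation_bin),
              positional_jitter = as.integer(positional_jitter),
              confounder_kmers = confounder_kmers)
  with(cfg, {
    stopifnot(n_transcripts > 0, read_length > 0,
              read_length_min > 0, read_length_min <= read_length,
              signal_fraction >= 0, signal_fraction <= 1,
              intronic_background_fraction >= 0,
              intronic_background_fraction <= 1,
              input_intronic_fraction >= 0, input_intronic_fraction <= 1,
              duplication_mean >= 1,
              exons_per_transcript[1] >= 1,
              exons_per_transcript[1] <= exons_per_transcript[2],
              exon_length[1] <= exon_length[2],
              intron_length[1] <= intron_length[2],
              grepl("^[ACGT]+$", motif))
  })
  class(cfg) <- "clip_sim_config"
  cfg
}

sample_range <- function(rng, n) {
  if (rng[1] == rng[2]) rep(rng[1], n) else sample(rng[1]:rng[2], n, TRUE)
}

#' Simulate a genome with a transcript annotation
#'
#' Transcripts are laid out non-overlapping on one chromosome of i.i.d.
#' uniform A/C/G/T sequence, alternating random strands; confounder k-mers
#' are seeded into exonic sequence in transcript orientation at an excess
#' rate over the uniform expectation, emulating compositional features of
#' coding sequence. Deterministic given `cfg$seed`.
#'
#' @param cfg a [clip_sim_config()]
#' @return list with `$genome` (named character vector), `$transcripts`
#'   (`transcript_models`)
#' @export
simulate_genome_and_annotation <- function(cfg) {
  set.seed(cfg$seed)
  pad <- 1000L
  cursor <- pad
  ex_rows <- vector("list", cfg$n_transcripts)
  for (i in seq_len(cfg$n_transcripts)) {
    n_ex <- sample_range(cfg$exons_per_transcript, 1L)
    ex_len <- sample_range(cfg$exon_length, n_ex)
    in_len <- if (n_ex > 1) sample_range(cfg$intron_length, n_ex - 1L)
              else integer()
    strand <- sample(c("+", "-"), 1L)
    starts <- cursor + cumsum(c(0L, ex_len[-n_ex] + in_len))
    ex_rows[[i]] <- data.frame(
      chrom = "chr1", start = starts, end = starts + ex_len,
      strand = strand,
      transcript_id = sprintf("t%04d", i),
      gene_id = sprintf("g%04d", i), stringsAsFactors = FALSE)
    cursor <- starts[n_ex] + ex_len[n_ex] + cfg$intergenic_gap
  }
  exons <- do.call(rbind, ex_rows)
  total_len <- cursor + pad
  letters_v <- sample(c("A", "C", "G", "T"), total_len, replace = TRUE)
  # seed confounder k-mers across each transcribed span (transcript
  # orientation): compositional bias is a property of genic sequence, so the
  # input library (which samples introns as pre-mRNA) carries it too
  spans <- do.call(rbind, lapply(ex_rows, function(ex) data.frame(
    start = min(ex$start), end = max(ex$end), strand = ex$strand[1])))
  for (ci in seq_along(cfg$confounder_kmers)) {
    kmer <- names(cfg$confounder_kmers)[ci]
    excess <- cfg$confounder_kmers[[ci]]
    if (excess <= 1) next
    k <- nchar(kmer)
    rate <- (excess - 1) / 4^k
    for (e in seq_len(nrow(spans))) {
      npos <- spans$end[e] - spans$start[e] - k + 1L
      if (npos < 1L) next
      n_plant <- rbinom(1L, npos, rate)
      if (!n_plant) next
      plant_at <- sample.int(npos, n_plant)
      km <- if (spans$strand[e] == "-") reverse_complement(kmer) else kmer
      km_chars <- strsplit(km, "", fixed = TRUE)[[1]]
      for (p in plant_at) {
        idx <- spans$start[e] + p - 1L + seq_len(k)
        letters_v[idx] <- km_chars
      }
    }
  }
  genome <- setNames(paste(letters_v, collapse = ""), "chr1")
  list(genome = genome, transcripts = transcript_models(exons))
}

#' Plant motif-bearing binding sites into exons
#'
#' Places sites uniformly over eligible exonic positions (at least
#' `read_length` from exon edges, pairwise separated by at least
#' `read_length`), writes the motif into the genome at the site center on the
#' transcript strand, and draws affinities from the configured log-normal.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [clip_sim_config()]
#' @param sim output of [simulate_genome_and_annotation()]
#' @param site_table optional data.frame (gene_id, affinity) fixing the
#'   site-to-gene assignment and affinities (used for paired "species"
#'   simulations that share binding targets)
#' @return list with `$sites` (data.frame: chrom, start, end, strand,
#'   site_id, transcript_id, gene_id, center, affinity) and `$genome` (the
#'   modified genome)
#' @export
plant_binding_sites <- function(cfg, sim, site_table = NULL) {
  set.seed(cfg$seed + 1L)
  tx <- sim$transcripts
  exons <- tx$exons
  margin <- cfg$read_length
  m <- nchar(cfg$motif)
  pools <- lapply(seq_len(nrow(exons)), function(e) {
    lo <- exons$start[e] + margin
    hi <- exons$end[e] - margin - 1L
    if (hi < lo) integer() else lo:hi
  })
  pool_df <- data.frame(
    center = unlist(pools),
    exon = rep(seq_len(nrow(exons)), lengths(pools)))
  n_sites <- if (is.null(site_table)) cfg$n_true_sites else nrow(site_table)
  if (n_sites == 0) {
    sites <- data.frame(chrom = character(), start = integer(),
                        end = integer(), strand = character(),
                        site_id = character(), transcript_id = character(),
                        gene_id = character(), center = integer(),
                        affinity = numeric(), stringsAsFactors = FALSE)
    return(list(sites = sites, genome = sim$genome))
  }
  pick_centers <- function(cand_idx, n_needed, taken, min_sep) {
    # greedy accept from a random permutation, enforcing separation
    got <- integer()
    for (i in sample(cand_idx)) {
      ctr <- pool_df$center[i]
      if (!any(abs(c(taken, pool_df$center[got]) - ctr) < min_sep)) {
        got <- c(got, i)
        if (length(got) == n_needed) break
      }
    }
    got
  }
  # prefer read_length separation (one peak per site); fall back to bare
  # non-overlap when a gene is too small to host its assigned sites
  pick_with_fallback <- function(cand_idx, n_needed, taken) {
    got <- pick_centers(cand_idx, n_needed, taken, cfg$read_length)
    if (length(got) < n_needed) {
      got2 <- pick_centers(setdiff(cand_idx, got),
                           n_needed - length(got),
                           c(taken, pool_df$center[got]), m)
      got <- c(got, got2)
    }
    if (length(got) < n_needed) {
      stop("not enough exonic space to plant the requested sites")
    }
    got
  }
  if (is.null(site_table)) {
    idx <- pick_with_fallback(seq_len(nrow(pool_df)), n_sites, integer())
    affinity <- rlnorm(n_sites, cfg$affinity_meanlog, cfg$affinity_sdlog)
  } else {
    idx <- integer(); affinity <- site_table$affinity
    for (g in sort(unique(site_table$gene_id))) {
      n_g <- sum(site_table$gene_id == g)
      ex_of_g <- which(exons$gene_id == g)
      cand <- which(pool_df$exon %in% ex_of_g)
      if (!length(cand)) stop("no exonic space on gene ", g)
      idx <- c(idx, pick_with_fallback(cand, n_g, pool_df$center[idx]))
    }
    # placement proceeded gene by gene; align affinities with that order
    affinity <- site_table$affinity[order(site_table$gene_id)]
  }
  ex_i <- pool_df$exon[idx]
  centers <- pool_df$center[idx]
  strand <- exons$strand[ex_i]
  start <- centers - (m %/% 2L)
  sites <- data.frame(
    chrom = exons$chrom[ex_i], start = start, end = start + m,
    strand = strand,
    site_id = sprintf("site_%d", seq_along(idx)),
    transcript_id = exons$transcript_id[ex_i],
    gene_id = exons$gene_id[ex_i],
    center = centers,
    affinity = affinity, stringsAsFactors = FALSE)
  # write the motif into the genome on the transcript strand
  letters_v <- strsplit(sim$genome[[1]], "", fixed = TRUE)[[1]]
  for (r in seq_len(nrow(sites))) {
    km <- if (sites$strand[r] == "-") reverse_complement(cfg$motif)
          else cfg$motif
    letters_v[(sites$start[r] + 1L):(sites$end[r])] <-
      strsplit(km, "", fixed = TRUE)[[1]]
  }
  genome <- setNames(paste(letters_v, collapse = ""), names(sim$genome))
  list(sites = sites, genome = genome)
}

# per-transcript exonic position pool, intron pool, and fragmentation weights
build_position_pools <- function(cfg, transcripts, bias_seed) {
  exons <- transcripts$exons
  tx_ids <- transcripts$transcripts$transcript_id
  ex_by_tx <- split(exons, exons$transcript_id)[tx_ids]
  expos <- lapply(ex_by_tx, function(ex) {
    unlist(lapply(seq_len(nrow(ex)), function(i) ex$start[i]:(ex$end[i] - 1L)))
  })
  inpos <- lapply(ex_by_tx, function(ex) {
    if (nrow(ex) < 2) return(integer())
    unlist(lapply(seq_len(nrow(ex) - 1L),
                  function(i) ex$end[i]:(ex$start[i + 1L] - 1L)))
  })
  set.seed(bias_seed)
  weights <- lapply(expos, function(pp) {
    if (!is.finite(cfg$fragmentation_bias_shape)) return(rep(1, length(pp)))
    nb <- ceiling(length(pp) / cfg$fragmentation_bin)
    w <- rgamma(nb, shape = cfg$fragmentation_bias_shape,
                rate = cfg$fragmentation_bias_shape)
    w[((seq_along(pp) - 1L) %/% cfg$fragmentation_bin) + 1L]
  })
  list(expos = expos, inpos = inpos, weights = weights, tx_ids = tx_ids,
       strand = setNames(transcripts$transcripts$strand, tx_ids),
       chrom = setNames(transcripts$transcripts$chrom, tx_ids))
}

# sample n background-style 5' positions: transcript ~ abundance, position
# uniform-or-biased over exons, intronic component uniform over introns
sample_background_positions <- function(n, pools, abundance,
                                        intronic_fraction, use_bias) {
  if (n == 0) {
    return(data.frame(chrom = character(), pos5 = integer(),
                      strand = character(), origin = character(),
                      stringsAsFactors = FALSE))
  }
  tx_ids <- pools$tx_ids
  ab <- abundance[tx_ids]
  n_intr <- rbinom(1L, n, intronic_fraction)
  has_intron <- lengths(pools$inpos) > 0
  if (!any(has_intron)) n_intr <- 0L
  n_ex <- n - n_intr
  out <- list()
  if (n_ex > 0) {
    tx_draw <- sample(tx_ids, n_ex, TRUE, prob = ab)
    cnt <- table(factor(tx_draw, levels = tx_ids))
    pos <- unlist(lapply(tx_ids[cnt > 0], function(t) {
      k <- cnt[[t]]
      pr <- if (use_bias) pools$weights[[t]] else NULL
      sample(pools$expos[[t]], k, TRUE, prob = pr)
    }))
    tx_rep <- rep(tx_ids[cnt > 0], cnt[cnt > 0])
    out$ex <- data.frame(chrom = unname(pools$chrom[tx_rep]), pos5 = pos,
                         strand = unname(pools$strand[tx_rep]),
                         origin = "background", stringsAsFactors = FALSE)
  }
  if (n_intr > 0) {
    tx_i <- tx_ids[has_intron]
    tx_draw <- sample(tx_i, n_intr, TRUE, prob = ab[tx_i])
    cnt <- table(factor(tx_draw, levels = tx_i))
    pos <- unlist(lapply(tx_i[cnt > 0], function(t) {
      sample(pools$inpos[[t]], cnt[[t]], TRUE)
    }))
    tx_rep <- rep(tx_i[cnt > 0], cnt[cnt > 0])
    out$intr <- data.frame(chrom = unname(pools$chrom[tx_rep]), pos5 = pos,
                           strand = unname(pools$strand[tx_rep]),
                           origin = "intronic", stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# reads are anchored at the 5' (crosslink-proximal) end; mapped spans vary
# per fragment because adapter trimming cuts reads to fragment length
pos5_to_reads <- function(df, cfg) {
  len <- sample(cfg$read_length_min:cfg$read_length, nrow(df), replace = TRUE)
  start <- ifelse(df$strand == "+", df$pos5, df$pos5 - len + 1L)
  aligned_reads(df$chrom, start, start + len, df$strand)
}

#' Simulate CLIP reads with planted signal and PCR duplication
#'
#' Unique fragments are a mixture: with probability `signal_fraction` a
#' fragment comes from a true site (chosen proportionally to affinity x host
#' abundance, 5' start jittered around the site center), otherwise from
#' background (transcript chosen proportionally to abundance; exonic
#' positions follow the shared fragmentation hotspots; a configured fraction
#' falls in introns). Each fragment is then amplified to `1 + Geometric`
#' copies. Deterministic given `cfg$seed`.
#'
#' @param cfg a [clip_sim_config()]
#' @param truth output of [plant_binding_sites()] (`$sites`)
#' @param pools position pools from the experiment orchestrator
#' @param abundance named per-transcript abundance vector
#' @return list with `$reads` (per-copy aligned reads), `$fragments` (unique
#'   fragments with origin, site_id and copy count)
#' @export
simulate_clip_reads <- function(cfg, truth, pools, abundance) {
  set.seed(cfg$seed + 2L)
  sites <- truth$sites
  n_frag <- cfg$clip_fragments
  n_sig <- if (nrow(sites)) rbinom(1L, n_frag, cfg$signal_fraction) else 0L
  frag <- list()
  if (n_sig > 0) {
    # fragment recovery at a site shares the fragmentation field of the
    # input library (same digestion of the same material)
    site_w <- vapply(seq_len(nrow(sites)), function(r) {
      t <- sites$transcript_id[r]
      i <- match(sites$center[r], pools$expos[[t]])
      if (is.na(i)) 1 else pools$weights[[t]][i]
    }, 0)
    pr <- sites$affinity * abundance[sites$transcript_id] * site_w
    si <- sample.int(nrow(sites), n_sig, TRUE, prob = pr)
    jit <- sample(seq(-cfg$positional_jitter, cfg$positional_jitter),
                  n_sig, TRUE)
    frag$sig <- data.frame(chrom = sites$chrom[si],
                           pos5 = sites$center[si] + jit,
                           strand = sites$strand[si],
                           origin = "signal",
                           site_id = sites$site_id[si],
                           stringsAsFactors = FALSE)
  }
  bg <- sample_background_positions(n_frag - n_sig, pools, abundance,
                                    cfg$intronic_background_fraction,
                                    use_bias = TRUE)
  if (nrow(bg)) {
    bg$site_id <- NA_character_
    frag$bg <- bg
  }
  fragments <- do.call(rbind, frag)
  rownames(fragments) <- NULL
  p <- 1 / cfg$duplication_mean
  fragments$copies <- 1L + rgeom(nrow(fragments), p)
  fragments$length <- sample(cfg$read_length_min:cfg$read_length,
                             nrow(fragments), replace = TRUE)
  idx <- rep(seq_len(nrow(fragments)), fragments$copies)
  fr <- fragments[idx, , drop = FALSE]
  start <- ifelse(fr$strand == "+", fr$pos5, fr$pos5 - fr$length + 1L)
  reads <- aligned_reads(fr$chrom, start, start + fr$length, fr$strand)
  list(reads = reads, fragments = fragments)
}

#' Simulate control reads (input RNA or RNAseq)
#'
#' Both controls track transcript abundance with no binding signal. Input RNA
#' is fragmented total RNA: it shares the fragmentation hotspots of the CLIP
#' background and includes the intronic component. RNAseq is exon-only and
#' uniform within transcripts.
#'
#' @param cfg a [clip_sim_config()]
#' @param pools position pools from the experiment orchestrator
#' @param abundance named per-transcript abundance vector
#' @param kind `"input_rna"` or `"rnaseq"`
#' @return aligned-read data.frame
#' @export
simulate_control_reads <- function(cfg, pools, abundance,
                                   kind = c("input_rna", "rnaseq")) {
  kind <- match.arg(kind)
  set.seed(cfg$seed + if (kind == "input_rna") 3L else 4L)
  n <- if (kind == "input_rna") cfg$input_reads else cfg$rnaseq_reads
  df <- sample_background_positions(
    n, pools, abundance,
    intronic_fraction = if (kind == "input_rna")
      cfg$input_intronic_fraction else 0,
    use_bias = kind == "input_rna")
  pos5_to_reads(df, cfg)
}

#' Run the full synthetic CLIP experiment
#'
#' Generates genome and annotation, draws abundances and fragmentation
#' hotspots, plants binding sites, and simulates CLIP, input-RNA and RNAseq
#' read sets. Fully deterministic given `cfg$seed`.
#'
#' @param cfg a [clip_sim_config()]
#' @param site_table optional (gene_id, affinity) table shared with a paired
#'   simulation (see [plant_binding_sites()])
#' @return a `clip_simulation` list: `$genome`, `$transcripts`, `$sites`,
#'   `$abundance`, `$clip_reads`, `$fragments`, `$input_reads`,
#'   `$rnaseq_reads`, `$config`
#' @export
simulate_clip_experiment <- function(cfg = clip_sim_config(),
                                     site_table = NULL) {
  base <- simulate_genome_and_annotation(cfg)
  set.seed(cfg$seed + 10L)
  abundance <- setNames(
    rlnorm(cfg$n_transcripts, cfg$abundance_meanlog, cfg$abundance_sdlog),
    base$transcripts$transcripts$transcript_id)
  truth <- plant_binding_sites(cfg, base, site_table)
  pools <- build_position_pools(cfg, base$transcripts,
                                bias_seed = cfg$seed + 11L)
  clip <- simulate_clip_reads(cfg, truth, pools, abundance)
  input <- simulate_control_reads(cfg, pools, abundance, "input_rna")
  rnaseq <- simulate_control_reads(cfg, pools, abundance, "rnaseq")
  structure(list(genome = truth$genome, transcripts = base$transcripts,
                 sites = truth$sites, abundance = abundance,
                 clip_reads = clip$reads, fragments = clip$fragments,
                 input_reads = input, rnaseq_reads = rnaseq,
                 config = cfg),
            class = "clip_simulation")
}

#' @export
print.clip_simulation <- function(x, ...) {
  cat(sprintf(paste0(
    "clip_simulation: %d-bp genome, %d transcripts, %d planted sites\n",
    "  CLIP reads %d (unique fragments %d), input %d, rnaseq %d\n"),
    nchar(x$genome[[1]]), nrow(x$transcripts$transcripts), nrow(x$sites),
    nrow(x$clip_reads), nrow(x$fragments), nrow(x$input_reads),
    nrow(x$rnaseq_reads)))
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Emits genome FASTA, GTF and BED12 annotation, per-copy read BEDs, truth
#' tables (sites, abundances, fragment origins) and a flat key=value config
#' echo.
#'
#' @param sim a `clip_simulation`
#' @param dir output directory (created if needed)
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_fasta(sim$genome, fp("genome.fa"))
  write_gtf(sim$transcripts, fp("annotation.gtf"))
  write_bed12(sim$transcripts, fp("annotation.bed12"))
  for (nm in c("clip_reads", "input_reads", "rnaseq_reads")) {
    r <- sim[[nm]]
    write_bed(genomic_intervals(r$chrom, r$start, r$end,
                                name = sprintf("r%d", seq_len(nrow(r))),
                                score = 0, strand = r$strand),
              fp(paste0(sub("_reads", "", nm), ".bed")))
  }
  write.table(sim$sites, fp("truth_sites.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(transcript_id = names(sim$abundance),
                         abundance = unname(sim$abundance)),
              fp("truth_abundance.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$fragments, fp("truth_fragments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  kv <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    paste0(k, "=", paste(if (!is.null(names(v)) && any(nzchar(names(v))))
      paste0(names(v), ":", v) else v, collapse = ","))
  }, "")
  writeLines(unname(kv), fp("config.echo"))
  invisible(dir)
}
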