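#' Simulation configuration
#'
#' The simulator generates a uniform-random multi-chromosome reference,
#' reads with controlled chimera geometry (plus optional reads supporting a
#' genuine mosaic deletion), truth alignments emitted directly from the
#' construction, and pore-like current traces. Traces are built from a
#' seeded k-mer level table with geometric per-base dwell and additive
#' Gaussian noise, preceded by a 1500-sample open-pore stalk. At artifact
#' chimera junctions the trace always carries a short noisy stall (the
#' junction-discontinuity cue of a re-ligated or pore-concatenated
#' molecule), and with probability `p_smooth_chimera` additionally a
#' low-amplitude low-variance smoothed segment; normal reads receive a
#' smoothed segment at a random interior anchor with probability
#' `p_smooth_normal`. The smoothed-segment probabilities default to the
#' prevalences observed by manual scoring of real ligation data (47% of
#' artifact chimeras, 13% of normal reads).
#'
#' @param n_chroms,chrom_len Reference shape (chromosomes x bases).
#' @param n_reads Number of reads.
#' @param read_len_meanlog,read_len_sdlog Log-normal read-length parameters
#'   for normal reads, bases.
#' @param min_read_len Floor on normal read length, bases.
#' @param chimera_rates Named fractions for `inverted_repeat`, `cross`,
#'   `gapped`; the remainder is normal.
#' @param chimera_frag_range Read-side fragment length range for chimeric
#'   sub-fragments, bases.
#' @param gap_range Reference gap range for gapped chimeras, bases.
#' @param recurrent_fraction Fraction of inverted-repeat chimeras anchored
#'   at one recurrent genomic site (creates a spurious clustered SV signal).
#' @param sv_del_fraction Fraction of reads supporting a genuine mosaic
#'   deletion (read through a deleted allele; no artifact signature in the
#'   trace).
#' @param sv_del_size Size of the genuine deletion, bases.
#' @param p_smooth_chimera,p_smooth_normal Smoothed-segment probabilities.
#' @param samples_per_base Mean dwell, samples per base.
#' @param level_mean,level_spread Mean and SD of the k-mer current levels
#'   (arbitrary digitized units).
#' @param noise_sd Additive Gaussian noise SD.
#' @param smooth_len_range Smoothed-segment length range, samples.
#' @param smooth_level,smooth_sd Smoothed-segment level (fraction of the
#'   mean level) and SD (fraction of `noise_sd`).
#' @param stall_len_range,stall_level,stall_sd Junction stall length range
#'   (samples), level (fraction of mean level) and SD (multiple of
#'   `noise_sd`).
#' @param head_len Open-pore stalk length prepended to every trace, samples.
#' @param kmer_k Level-table context size.
#' @param seed Master seed; every simulator output is a deterministic
#'   function of the config including this seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 2, chrom_len = 100000, n_reads = 500,
                       read_len_meanlog = log(3000), read_len_sdlog = 0.35,
                       min_read_len = 800,
                       chimera_rates = c(inverted_repeat = 0.05,
                                         cross = 0.01, gapped = 0.01),
                       chimera_frag_range = c(600, 2500),
                       gap_range = c(6000, 20000),
                       recurrent_fraction = 0,
                       sv_del_fraction = 0,
                       sv_del_size = 800,
                       p_smooth_chimera = 0.47, p_smooth_normal = 0.13,
                       samples_per_base = 10, level_mean = 90,
                       level_spread = 10, noise_sd = 1.5,
                       smooth_len_range = c(300, 800),
                       smooth_level = 0.6, smooth_sd = 0.1,
                       stall_len_range = c(20, 80),
                       stall_level = 1.25, stall_sd = 2.0,
                       head_len = 1500, kmer_k = 5, seed = 1L) {
  stopifnot(sum(chimera_rates) + sv_del_fraction <= 1,
            all(chimera_rates >= 0),
            p_smooth_chimera >= 0, p_smooth_chimera <= 1,
            p_smooth_normal >= 0, p_smooth_normal <= 1)
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' Simulate a reference genome
#'
#' I.i.d. uniform bases over the configured chromosome layout; deterministic
#' per seed.
#'
#' @param config A [sim_config()].
#' @return A named `DNAStringSet` (`chr1`, `chr2`, ...).
#' @export
simulate_reference <- function(config = sim_config()) {
  seqs <- with_seed(config$seed, {
    vapply(seq_len(config$n_chroms), function(i) {
      paste(sample(c("A", "C", "G", "T"), config$chrom_len, replace = TRUE),
            collapse = "")
    }, character(1))
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- paste0("chr", seq_len(config$n_chroms))
  out
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Simulate reads with controlled chimera geometry
#'
#' Normal reads are contiguous reference substrings on either strand.
#' Inverted-repeat chimeras join a fragment with the reverse complement of a
#' nearby fragment of the same chromosome; cross chimeras join fragments of
#' two chromosomes; gapped chimeras join same-strand fragments separated by
#' more than the detector's gap threshold. Genuine-deletion reads (when
#' `sv_del_fraction > 0`) traverse a deleted allele: two same-strand
#' fragments separated by `sv_del_size` on the reference, with no artifact
#' signature in the trace. Truth alignments are emitted from the
#' construction itself, so downstream detection is tested against geometry,
#' not aligner behaviour.
#'
#' @param reference `DNAStringSet` from [simulate_reference()].
#' @param config A [sim_config()].
#' @return A list: `reads` (named character vector of sequences), `frags`
#'   (truth fragment table), `truth` (`data.frame`: `read_id`, `true_type`,
#'   `junction_base`, `is_sv_read`).
#' @export
simulate_reads <- function(reference, config = sim_config()) {
  with_seed(config$seed + 1L, simulate_reads_impl(reference, config))
}

simulate_reads_impl <- function(reference, config) {
  refs <- as.character(reference)
  chroms <- names(refs)
  clen <- config$chrom_len
  rates <- config$chimera_rates
  types <- c(names(rates), "sv_del", "normal")
  probs <- c(rates, config$sv_del_fraction,
             1 - sum(rates) - config$sv_del_fraction)
  draw_type <- sample(types, config$n_reads, replace = TRUE, prob = probs)
  frag_len <- function() sample(config$chimera_frag_range[1]:config$chimera_frag_range[2], 1)
  # recurrent inverted-repeat site, fixed per simulation
  rec_chrom <- sample(chroms, 1)
  rec_lenA <- frag_len()
  rec_start <- sample.int(clen - 3L * config$chimera_frag_range[2], 1)
  # genuine deletion locus
  del_chrom <- chroms[1]
  del_pos <- sample.int(clen - 4L * config$chimera_frag_range[2], 1) +
    config$chimera_frag_range[2]

  reads <- character(config$n_reads)
  truth <- vector("list", config$n_reads)
  frag_rows <- vector("list", config$n_reads)
  mk_frag <- function(id, rl, qs, qe, strand, target, ts, te, supp) {
    data.frame(read_id = id, read_len = rl, q_start = qs, q_end = qe,
               strand = strand, target = target, t_start = ts, t_end = te,
               mapq = 60L, is_supplementary = supp, stringsAsFactors = FALSE)
  }
  for (i in seq_len(config$n_reads)) {
    id <- sprintf("read%05d", i)
    tp <- draw_type[i]
    if (tp == "normal") {
      L <- max(config$min_read_len,
               round(stats::rlnorm(1, config$read_len_meanlog, config$read_len_sdlog)))
      L <- min(L, clen - 1L)
      chrom <- sample(chroms, 1)
      p <- sample.int(clen - L, 1) - 1L       # 0-based
      strand <- sample(c("+", "-"), 1)
      s <- substr(refs[[chrom]], p + 1L, p + L)
      reads[i] <- if (strand == "+") s else revcomp_chr(s)
      frag_rows[[i]] <- mk_frag(id, L, 0L, L, strand, chrom, p, p + L, FALSE)
      truth[[i]] <- data.frame(read_id = id, true_type = "normal",
                               junction_base = NA_integer_, is_sv_read = FALSE,
                               stringsAsFactors = FALSE)
      next
    }
    if (tp == "sv_del") {
      lenA <- frag_len(); lenB <- frag_len()
      chrom <- del_chrom
      pA <- del_pos - lenA                    # fragment A ends at the deletion
      pB <- del_pos + config$sv_del_size      # fragment B starts after it
      s <- paste0(substr(refs[[chrom]], pA + 1L, pA + lenA),
                  substr(refs[[chrom]], pB + 1L, pB + lenB))
      L <- lenA + lenB
      reads[i] <- s
      frag_rows[[i]] <- rbind(
        mk_frag(id, L, 0L, lenA, "+", chrom, pA, pA + lenA, FALSE),
        mk_frag(id, L, lenA, L, "+", chrom, pB, pB + lenB, TRUE))
      truth[[i]] <- data.frame(read_id = id, true_type = "normal",
                               junction_base = lenA, is_sv_read = TRUE,
                               stringsAsFactors = FALSE)
      next
    }
    # artifact chimeras
    recurrent <- tp == "inverted_repeat" &&
      stats::runif(1) < config$recurrent_fraction
    lenA <- if (recurrent) rec_lenA else frag_len()
    lenB <- frag_len()
    L <- lenA + lenB
    if (tp == "inverted_repeat") {
      chrom <- if (recurrent) rec_chrom else sample(chroms, 1)
      pA <- if (recurrent) rec_start else
        sample.int(clen - (lenA + lenB + 600L), 1) - 1L
      d <- sample.int(500L, 1)               # nearby, downstream
      pB <- pA + lenA + d
      sA <- substr(refs[[chrom]], pA + 1L, pA + lenA)
      sB <- substr(refs[[chrom]], pB + 1L, pB + lenB)
      reads[i] <- paste0(sA, revcomp_chr(sB))
      frag_rows[[i]] <- rbind(
        mk_frag(id, L, 0L, lenA, "+", chrom, pA, pA + lenA, FALSE),
        mk_frag(id, L, lenA, L, "-", chrom, pB, pB + lenB, TRUE))
    } else if (tp == "cross") {
      two <- sample(chroms, 2)
      pA <- sample.int(clen - lenA, 1) - 1L
      pB <- sample.int(clen - lenB, 1) - 1L
      reads[i] <- paste0(substr(refs[[two[1]]], pA + 1L, pA + lenA),
                         substr(refs[[two[2]]], pB + 1L, pB + lenB))
      frag_rows[[i]] <- rbind(
        mk_frag(id, L, 0L, lenA, "+", two[1], pA, pA + lenA, FALSE),
        mk_frag(id, L, lenA, L, "+", two[2], pB, pB + lenB, TRUE))
    } else { # gapped
      chrom <- sample(chroms, 1)
      gap <- sample(config$gap_range[1]:config$gap_range[2], 1)
      pA <- sample.int(clen - (lenA + gap + lenB), 1) - 1L
      pB <- pA + lenA + gap
      reads[i] <- paste0(substr(refs[[chrom]], pA + 1L, pA + lenA),
                         substr(refs[[chrom]], pB + 1L, pB + lenB))
      frag_rows[[i]] <- rbind(
        mk_frag(id, L, 0L, lenA, "+", chrom, pA, pA + lenA, FALSE),
        mk_frag(id, L, lenA, L, "+", chrom, pB, pB + lenB, TRUE))
    }
    truth[[i]] <- data.frame(read_id = id, true_type = tp,
                             junction_base = lenA, is_sv_read = FALSE,
                             stringsAsFactors = FALSE)
  }
  names(reads) <- sprintf("read%05d", seq_len(config$n_reads))
  list(reads = reads, frags = do.call(rbind, frag_rows),
       truth = do.call(rbind, truth))
}

base_codes <- c(A = 0L, C = 1L, G = 2L, T = 3L)

kmer_level_table <- function(config) {
  with_seed(config$seed + 2L,
            stats::rnorm(4^config$kmer_k, config$level_mean, config$level_spread))
}

seq_levels <- function(seq, config, table) {
  k <- config$kmer_k
  d <- base_codes[strsplit(seq, "", fixed = TRUE)[[1]]]
  L <- length(d)
  if (L < k) return(rep(config$level_mean, L))
  idx <- integer(L - k + 1L)
  for (j in seq_len(k)) {
    idx <- idx + d[j:(L - k + j)] * 4L^(k - j)
  }
  lev <- table[idx + 1L]
  c(lev, rep(lev[length(lev)], k - 1L))  # tail bases reuse the last context
}

#' Simulate the current trace of one read
#'
#' Per-base levels from the seeded k-mer table, geometric dwell, additive
#' Gaussian noise, an open-pore stalk of `head_len` samples, and the
#' junction insertions described in [sim_config()]. The returned trace
#' carries an exact base-to-signal map; the truth junction sample is the
#' first sample of the base following the junction (insertions sit
#' immediately before it).
#'
#' @param seq Read sequence (character).
#' @param truth One truth row from [simulate_reads()].
#' @param config A [sim_config()].
#' @param table K-mer level table from the simulation (internal reuse).
#' @param seed Per-read seed.
#' @return A list: `signal` ([raw_signal()]), `junction_sample`,
#'   `anchor_sample` (normal-read anchor, `NA` for chimeras),
#'   `has_smoothed_segment`.
#' @export
simulate_signal <- function(seq, truth, config = sim_config(),
                            table = kmer_level_table(config), seed = 1L) {
  with_seed(seed, simulate_signal_impl(seq, truth, config, table))
}

simulate_signal_impl <- function(seq, truth, config, table) {
  L <- nchar(seq)
  lev <- seq_levels(seq, config, table)
  dwell <- stats::rgeom(L, 1 / config$samples_per_base) + 1L
  starts <- c(0L, cumsum(dwell)[-L])          # 0-based body sample start per base
  body <- rep(lev, dwell)
  if (config$noise_sd > 0) body <- body + stats::rnorm(length(body), 0, config$noise_sd)
  chimeric <- truth$true_type != "normal"
  has_smooth <- FALSE
  insert <- numeric(0)
  insert_base <- NA_integer_
  anchor_base <- NA_integer_
  if (chimeric) {
    insert_base <- truth$junction_base
    stall_len <- sample(config$stall_len_range[1]:config$stall_len_range[2], 1)
    insert <- stats::rnorm(stall_len, config$stall_level * config$level_mean,
                           config$stall_sd * max(config$noise_sd, 1e-3))
    if (stats::runif(1) < config$p_smooth_chimera) {
      has_smooth <- TRUE
      sl <- sample(config$smooth_len_range[1]:config$smooth_len_range[2], 1)
      insert <- c(stats::rnorm(sl, config$smooth_level * config$level_mean,
                               config$smooth_sd * max(config$noise_sd, 1e-6)),
                  insert)
    }
  } else {
    anchor_base <- as.integer(round(stats::runif(1, 0.15, 0.85) * L))
    if (stats::runif(1) < config$p_smooth_normal) {
      has_smooth <- TRUE
      insert_base <- anchor_base
      sl <- sample(config$smooth_len_range[1]:config$smooth_len_range[2], 1)
      insert <- stats::rnorm(sl, config$smooth_level * config$level_mean,
                             config$smooth_sd * max(config$noise_sd, 1e-6))
    }
  }
  if (length(insert) && !is.na(insert_base)) {
    at <- starts[min(insert_base + 1L, L)]    # splice before this base
    body <- c(body[seq_len(at)], insert, body[seq(at + 1L, length(body))])
    shift <- seq_along(starts) > insert_base  # bases at/after the junction move
    starts[shift] <- starts[shift] + length(insert)
  }
  head_sig <- stats::rnorm(config$head_len, 1.2 * config$level_mean,
                           3 * max(config$noise_sd, 1e-3))
  samples <- c(head_sig, body)
  map <- as.integer(config$head_len + starts)
  sig <- raw_signal(truth$read_id, samples, base_to_signal = map,
                    source = "simulated")
  junction_sample <- if (chimeric) map[truth$junction_base + 1L] else NA_integer_
  anchor_sample <- if (!chimeric) map[anchor_base + 1L] else NA_integer_
  list(signal = sig, junction_sample = junction_sample,
       anchor_sample = anchor_sample, has_smoothed_segment = has_smooth)
}

#' Run the full simulator
#'
#' Generates reference, reads, truth alignments and (optionally) current
#' traces in one call; fully deterministic per `(config, seed)`.
#'
#' @param config A [sim_config()].
#' @param signals Also simulate current traces (default `TRUE`).
#' @return A list: `reference` (`DNAStringSet`), `reads`, `frags` (truth
#'   fragment table), `truth` (with `junction_sample`, `anchor_sample`,
#'   `has_smoothed_segment` when signals are simulated), `signals` (named
#'   list of [raw_signal()] or `NULL`), `read_lens` (named vector),
#'   `config`.
#' @export
simulate_run <- function(config = sim_config(), signals = TRUE) {
  reference <- simulate_reference(config)
  rd <- simulate_reads(reference, config)
  truth <- rd$truth
  read_lens <- stats::setNames(nchar(rd$reads), names(rd$reads))
  sigs <- NULL
  if (signals) {
    table <- kmer_level_table(config)
    truth$junction_sample <- NA_integer_
    truth$anchor_sample <- NA_integer_
    truth$has_smoothed_segment <- FALSE
    sigs <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      ss <- simulate_signal(rd$reads[[truth$read_id[i]]], truth[i, ],
                            config, table,
                            seed = (config$seed * 1000003L + i) %% .Machine$integer.max)
      sigs[[i]] <- ss$signal
      truth$junction_sample[i] <- ss$junction_sample
      truth$anchor_sample[i] <- ss$anchor_sample
      truth$has_smoothed_segment[i] <- ss$has_smoothed_segment
    }
    names(sigs) <- truth$read_id
  }
  list(reference = reference, reads = rd$reads, frags = rd$frags,
       truth = truth, signals = sigs, read_lens = read_lens, config = config)
}

#' Write a simulation to disk
#'
#' Writes `reference.fa`, `reads.fastq` (constant quality), `truth.paf`,
#' `truth.tsv` and `signals.tsv` under a directory.
#'
#' @param sim Result of [simulate_run()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$reference, file.path(dir, "reference.fa"))
  reads <- Biostrings::DNAStringSet(sim$reads)
  qual <- Biostrings::BStringSet(vapply(Biostrings::width(reads), function(w) {
    paste(rep("I", w), collapse = "")
  }, character(1)))
  fq <- Biostrings::QualityScaledDNAStringSet(
    reads, Biostrings::PhredQuality(qual))
  Biostrings::writeQualityScaledXStringSet(fq, file.path(dir, "reads.fastq"))
  write_paf(sim$frags, file.path(dir, "truth.paf"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(sim$signals)) {
    write_signals(sim$signals, file.path(dir, "signals.tsv"))
  }
  invisible(dir)
}
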