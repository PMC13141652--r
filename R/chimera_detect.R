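#' Detector configuration for chimera typing
#'
#' Thresholds of the rule-based typing of split-read alignments. Defaults are
#' the published criteria: each fragment must span more than 500 bp of the
#' read, the read-space overlap ratio between the two fragments must be below
#' 0.05, their combined read-side span must exceed 80% of the read length,
#' the reference gap defining a gapped chimera is 5000 bp, the homology
#' ceiling for cross/gapped calls is 5%, and candidate pairs are pre-screened
#' at an overlap ratio of 0.2 (above which split alignments are treated as
#' multi-mapping noise rather than chimeric structure).
#'
#' @param min_frag_len Minimum read-side span per fragment, bases.
#' @param max_overlap_ratio Per-type overlap-ratio gate.
#' @param min_combined_fraction Minimum (span_a + span_b) / read_len.
#' @param min_gap_distance Minimum reference gap for a gapped chimera, bases.
#' @param max_homology Maximum allowed similarity between the two reference
#'   intervals of a cross/gapped pair, fraction of the shorter interval.
#' @param candidate_overlap_screen Pre-filter: pairs with overlap ratio at or
#'   above this value are never considered chimeric.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(min_frag_len = 500,
                            max_overlap_ratio = 0.05,
                            min_combined_fraction = 0.8,
                            min_gap_distance = 5000,
                            max_homology = 0.05,
                            candidate_overlap_screen = 0.2) {
  stopifnot(min_frag_len >= 0, max_overlap_ratio >= 0,
            min_combined_fraction >= 0, min_gap_distance >= 0,
            max_homology >= 0,
            max_overlap_ratio <= candidate_overlap_screen)
  structure(list(min_frag_len = min_frag_len,
                 max_overlap_ratio = max_overlap_ratio,
                 min_combined_fraction = min_combined_fraction,
                 min_gap_distance = min_gap_distance,
                 max_homology = max_homology,
                 candidate_overlap_screen = candidate_overlap_screen),
            class = "detector_config")
}

#' Read-space overlap ratio between two fragments of one read
#'
#' overlap_ratio = overlap_len / min(map_len_a, map_len_b), where the overlap
#' is taken on read coordinates and map_len is each fragment's read-side
#' aligned span. Symmetric in its arguments; 0 for disjoint fragments, 1 for
#' identical intervals.
#'
#' @param frag_a,frag_b Single-row fragment records (or lists) with
#'   `q_start`/`q_end`.
#' @return Dimensionless ratio, >= 0.
#' @export
compute_overlap_ratio <- function(frag_a, frag_b) {
  la <- frag_a$q_end - frag_a$q_start
  lb <- frag_b$q_end - frag_b$q_start
  if (la <= 0 || lb <= 0) stop("fragment with non-positive read-side span")
  ov <- max(0, min(frag_a$q_end, frag_b$q_end) - max(frag_a$q_start, frag_b$q_start))
  ov / min(la, lb)
}

#' Sequence similarity between two reference intervals
#'
#' Fraction of the shorter sequence covered by the best local alignment
#' between the two sequences, taking the better of the two orientations
#' (plus strand and reverse complement). Scoring: match +1, mismatch -2, gap
#' open -4, gap extend -1. Local alignments shorter than `min_aln_len` are
#' ignored (similarity 0), so unrelated random sequences score ~0.
#'
#' @param seq_a,seq_b Nucleotide strings or `DNAString`s, non-empty.
#' @param min_aln_len Minimum local-alignment length reported (default 50).
#' @return Similarity fraction in `[0, 1]`.
#' @export
homology_similarity <- function(seq_a, seq_b, min_aln_len = 50) {
  seq_a <- toupper(as.character(seq_a))
  seq_b <- toupper(as.character(seq_b))
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  if (grepl("[^ACGTRYSWKMBDHVN]", seq_a) || grepl("[^ACGTRYSWKMBDHVN]", seq_b)) {
    stop("non-IUPAC characters in sequence")
  }
  a <- Biostrings::DNAString(seq_a)
  b <- Biostrings::DNAString(seq_b)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = FALSE)
  aln_len <- function(subject) {
    al <- Biostrings::pairwiseAlignment(a, subject, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 4, gapExtension = 1)
    w <- Biostrings::nchar(al)  # aligned region length incl. gaps
    if (length(w) == 0 || Biostrings::score(al) <= 0) 0L else as.integer(w)
  }
  best <- max(aln_len(b), aln_len(Biostrings::reverseComplement(b)))
  if (best < min_aln_len) return(0)
  min(1, best / min(length(a), length(b)))
}

#' Build a reference accessor from a FASTA file or DNAStringSet
#'
#' Returns a function `f(target, start, end)` (0-based half-open) yielding
#' the reference subsequence as a character string, for use as `ref_fetch`
#' in [classify_read()].
#'
#' @param ref Path to a FASTA file or a `DNAStringSet`.
#' @return A fetch function.
#' @export
reference_accessor <- function(ref) {
  seqs <- if (is.character(ref)) Biostrings::readDNAStringSet(ref) else ref
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  function(target, start, end) {
    if (!target %in% names(seqs)) stop("unknown reference sequence: ", target)
    n <- length(seqs[[target]])
    start <- max(0L, as.integer(start))
    end <- min(n, as.integer(end))
    if (end <= start) stop("empty reference interval requested")
    as.character(Biostrings::subseq(seqs[[target]], start + 1L, end))
  }
}

# Evaluate one primary/supplementary pair against the shared gates and the
# per-type geometry. Returns a one-row data.frame.
classify_pair <- function(read_id, read_len, pa, pb, config, ref_fetch) {
  la <- pa$q_end - pa$q_start
  lb <- pb$q_end - pb$q_start
  ov <- compute_overlap_ratio(pa, pb)
  comb <- (la + lb) / read_len
  # junction midpoint in read space: middle of the overlap, or of the gap
  # between the two read intervals (identical formula either way)
  bp <- (min(pa$q_end, pb$q_end) + max(pa$q_start, pb$q_start)) %/% 2
  bp <- max(0L, min(as.integer(read_len), as.integer(bp)))
  out <- data.frame(read_id = read_id, chimera_type = "normal",
                    breakpoint = bp, overlap_ratio = ov,
                    combined_fraction = comb, homology = NA_real_,
                    homology_checked = FALSE, warning = "",
                    stringsAsFactors = FALSE)
  gates <- la > config$min_frag_len && lb > config$min_frag_len &&
    ov < config$candidate_overlap_screen &&
    ov < config$max_overlap_ratio &&
    comb > config$min_combined_fraction
  if (!gates) return(out)
  same_target <- pa$target == pb$target
  if (same_target && pa$strand != pb$strand) {
    out$chimera_type <- "inverted_repeat"
    return(out)
  }
  need_hom <- !same_target ||
    (same_target && pa$strand == pb$strand &&
       max(pa$t_start, pb$t_start) - min(pa$t_end, pb$t_end) > config$min_gap_distance)
  if (!need_hom) return(out)
  if (is.null(ref_fetch)) {
    out$warning <- "homology unverifiable: no reference supplied"
    return(out)
  }
  sim <- homology_similarity(ref_fetch(pa$target, pa$t_start, pa$t_end),
                             ref_fetch(pb$target, pb$t_start, pb$t_end))
  out$homology <- sim
  out$homology_checked <- TRUE
  if (sim >= config$max_homology) return(out)
  out$chimera_type <- if (!same_target) "cross" else "gapped"
  out
}

#' Classify one read's fragments into a chimera type
#'
#' Applies the rule set to a read's split alignments. On reads with more than
#' two fragments, the primary is evaluated against each supplementary and the
#' pair maximizing combined read coverage is kept. The shared gates (fragment
#' length, overlap ratio, combined fraction) are followed by disjoint
#' geometry rules: inverted repeat = same chromosome, opposite strands; cross
#' = different chromosomes with negligible homology between the two reference
#' intervals; gapped = same chromosome, same strand, reference gap above the
#' configured distance, again with negligible homology. Everything else is
#' normal.
#'
#' @param frags Fragment rows of a single read (data.frame).
#' @param config A [detector_config()].
#' @param ref_fetch Optional reference accessor ([reference_accessor()]);
#'   without it, cross/gapped candidates are left normal with a warning flag.
#' @return One-row `data.frame`: `read_id`, `chimera_type`, `breakpoint`
#'   (read offset), `overlap_ratio`, `combined_fraction`, `homology`,
#'   `homology_checked`, `warning`.
#' @export
classify_read <- function(frags, config = detector_config(), ref_fetch = NULL) {
  read_id <- frags$read_id[1]
  read_len <- frags$read_len[1]
  normal <- data.frame(read_id = read_id, chimera_type = "normal",
                       breakpoint = NA_integer_, overlap_ratio = NA_real_,
                       combined_fraction = NA_real_, homology = NA_real_,
                       homology_checked = FALSE, warning = "",
                       stringsAsFactors = FALSE)
  if (nrow(frags) < 2L || !any(frags$is_supplementary)) return(normal)
  prim <- which(!frags$is_supplementary)
  if (!length(prim)) prim <- 1L
  prim <- prim[1L]
  supp <- setdiff(seq_len(nrow(frags)), prim)
  # pick the primary/supplementary pair with maximal combined read coverage
  cov <- vapply(supp, function(j) {
    (frags$q_end[prim] - frags$q_start[prim]) + (frags$q_end[j] - frags$q_start[j])
  }, numeric(1))
  j <- supp[which.max(cov)]
  classify_pair(read_id, read_len,
                frags[prim, , drop = FALSE], frags[j, , drop = FALSE],
                config, ref_fetch)
}

#' Classify every read in a fragment table
#'
#' @param frags Full fragment table (already MapQ-filtered).
#' @param config A [detector_config()].
#' @param ref_fetch Optional reference accessor.
#' @return A `data.frame` of calls, one row per read.
#' @export
classify_reads <- function(frags, config = detector_config(), ref_fetch = NULL) {
  grouped <- group_by_read(frags)
  pieces <- split(grouped$fragments, grouped$fragments$read_id)
  calls <- lapply(pieces, classify_read, config = config, ref_fetch = ref_fetch)
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  calls
}

#' Summarize chimera calls
#'
#' Per-type counts and ratios over all reads, the total FP chimeric ratio,
#' the inverted-repeat share of the total, and the chimera ratio binned by
#' read length in 1000 bp intervals (when read lengths are supplied).
#'
#' @param calls Call table from [classify_reads()] (every read exactly once).
#' @param read_lens Optional named vector of read lengths (names = read ids)
#'   for the length-binned ratios.
#' @return A list with `counts`, `ratios` (fractions of all reads), `total_reads`,
#'   `fp_ratio`, `inverted_repeat_share` (fraction of chimeric calls that are
#'   inverted repeats; `NA` when there are none) and `by_length` (or `NULL`).
#' @export
summarize_chimeras <- function(calls, read_lens = NULL) {
  types <- c("inverted_repeat", "cross", "gapped", "normal")
  n <- nrow(calls)
  if (n == 0L) {
    return(list(counts = stats::setNames(integer(4), types),
                ratios = stats::setNames(rep(NA_real_, 4), types),
                total_reads = 0L, fp_ratio = NA_real_,
                inverted_repeat_share = NA_real_, by_length = NULL))
  }
  stopifnot(!anyDuplicated(calls$read_id))
  counts <- stats::setNames(vapply(types, function(t) sum(calls$chimera_type == t), 0L), types)
  ratios <- counts / n
  n_chim <- sum(counts[c("inverted_repeat", "cross", "gapped")])
  fp_ratio <- n_chim / n
  share <- if (n_chim > 0) unname(counts["inverted_repeat"]) / n_chim else NA_real_
  by_length <- NULL
  if (!is.null(read_lens)) {
    rl <- read_lens[calls$read_id]
    bin <- (as.integer(rl) %/% 1000L) * 1000L
    dt <- data.table::data.table(bin = bin, chim = calls$chimera_type != "normal")
    by_length <- as.data.frame(dt[, list(n_reads = .N, chimera_ratio = mean(chim)),
                                  by = "bin"][order(bin)])
  }
  list(counts = counts, ratios = ratios, total_reads = n, fp_ratio = fp_ratio,
       inverted_repeat_share = share, by_length = by_length)
}
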