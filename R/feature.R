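#' Configuration of the smoothed-segment detector
#'
#' The smoothed segment is a run of low-amplitude, low-variance current
#' samples embedded in an otherwise normal trace, enriched at the junctions
#' of artifact chimeric reads. The detector tiles the flank around a
#' breakpoint with non-overlapping windows, computes each window's mean and
#' standard deviation, and fires when enough consecutive windows are both
#' quieter (SD below `sd_alpha` times the global SD) and lower (mean below
#' `mean_beta` times the global mean) than the trace at large.
#'
#' @param window_w Window width, samples.
#' @param flank_f Search radius around the breakpoint, samples.
#' @param min_run Minimum number of consecutive qualifying windows.
#' @param sd_alpha Window-SD gate as a fraction of the global SD.
#' @param mean_beta Window-mean gate as a fraction of the global mean.
#' @param head_trim Samples excluded from the global statistics at the trace
#'   start (the pre-sequencing open-pore stalk).
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(window_w = 50, flank_f = 2000, min_run = 5,
                           sd_alpha = 0.3, mean_beta = 1.0, head_trim = 1500) {
  stopifnot(window_w > 0, flank_f > 0, min_run > 0, sd_alpha > 0, mean_beta > 0)
  structure(list(window_w = as.integer(window_w), flank_f = as.integer(flank_f),
                 min_run = as.integer(min_run), sd_alpha = sd_alpha,
                 mean_beta = mean_beta, head_trim = as.integer(head_trim)),
            class = "feature_config")
}

#' Detect a smoothed segment near a breakpoint
#'
#' Scans `[bp_index - flank_f, bp_index + flank_f]` with non-overlapping
#' windows of `window_w` samples and reports whether a run of at least
#' `min_run` consecutive windows is simultaneously low-variance
#' (SD < `sd_alpha` x global SD) and low-amplitude (mean < `mean_beta` x
#' global mean). Global statistics are computed over the whole trace
#' excluding its first `head_trim` samples. Degenerate flat traces (global
#' SD below 1e-9) never fire: the ratio gates are undefined there.
#'
#' @param signal A [raw_signal()].
#' @param bp_index 0-based signal index of the breakpoint.
#' @param config A [feature_config()].
#' @return A one-row `data.frame`: `read_id`, `has_smoothed_segment`,
#'   `segment_start`, `segment_end` (0-based half-open signal indices, `NA`
#'   when absent), `segment_sd_ratio`, `segment_mean_ratio`,
#'   `distance_to_breakpoint` (samples from `bp_index` to the segment
#'   midpoint).
#' @export
detect_smoothed_segment <- function(signal, bp_index, config = feature_config()) {
  stopifnot(bp_index >= 0, bp_index < signal$sample_count)
  none <- data.frame(read_id = signal$read_id, has_smoothed_segment = FALSE,
                     segment_start = NA_integer_, segment_end = NA_integer_,
                     segment_sd_ratio = NA_real_, segment_mean_ratio = NA_real_,
                     distance_to_breakpoint = NA_real_,
                     stringsAsFactors = FALSE)
  x <- signal$samples
  body <- if (signal$sample_count > config$head_trim) {
    x[(config$head_trim + 1L):signal$sample_count]
  } else x
  g_mean <- mean(body)
  g_sd <- stats::sd(body)
  if (!is.finite(g_sd) || g_sd < 1e-9) return(none)
  lo <- max(0L, bp_index - config$flank_f)
  hi <- min(signal$sample_count, bp_index + config$flank_f + 1L)
  if (hi - lo < config$window_w) return(none)
  n_win <- (hi - lo) %/% config$window_w
  idx <- lo + seq_len(n_win * config$window_w)  # 1-based into x
  m <- matrix(x[idx], nrow = config$window_w)
  w_mean <- colMeans(m)
  w_sd <- sqrt(colSums(sweep(m, 2, w_mean)^2) / (config$window_w - 1L))
  hit <- w_sd < config$sd_alpha * g_sd & w_mean < config$mean_beta * g_mean
  r <- rle(hit)
  runs <- which(r$values & r$lengths >= config$min_run)
  if (!length(runs)) return(none)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # among qualifying runs keep the one closest to the breakpoint
  w0 <- lo + (starts[runs] - 1L) * config$window_w       # 0-based sample start
  w1 <- lo + ends[runs] * config$window_w                # 0-based exclusive end
  mid <- (w0 + w1) / 2
  k <- which.min(abs(mid - bp_index))
  sel <- seq(starts[runs[k]], ends[runs[k]])
  data.frame(read_id = signal$read_id, has_smoothed_segment = TRUE,
             segment_start = as.integer(w0[k]), segment_end = as.integer(w1[k]),
             segment_sd_ratio = mean(w_sd[sel]) / g_sd,
             segment_mean_ratio = mean(w_mean[sel]) / g_mean,
             distance_to_breakpoint = mid[k] - bp_index,
             stringsAsFactors = FALSE)
}

#' Draw a pseudo-breakpoint for a normal read
#'
#' Normal reads have no junction; when comparing smoothed-segment prevalence
#' across types each normal read gets a reproducible anchor drawn uniformly
#' from the interior of its trace, away from the trimmed head and the flank
#' margins. The draw is keyed on the read id and a seed so it is independent
#' of processing order.
#'
#' @param signal A [raw_signal()].
#' @param config A [feature_config()].
#' @param seed Integer seed.
#' @return 0-based signal index.
#' @export
pseudo_breakpoint <- function(signal, config = feature_config(), seed = 1L) {
  lo <- config$head_trim + config$flank_f
  hi <- signal$sample_count - config$flank_f
  if (hi <= lo) return(as.integer(signal$sample_count %/% 2))
  r <- with_seed(as.integer(seed) + id_key(signal$read_id), stats::runif(1))
  as.integer(lo + floor(r * (hi - lo)))
}

#' Smoothed-segment prevalence by chimera type
#'
#' Per-type fraction of reads with a detected smoothed segment near their
#' breakpoint, with pairwise two-sided Mann-Whitney U tests between types.
#' When the table spans several sequencing runs (a `run` column), the tests
#' compare per-run fractions, mirroring run-level comparisons; with a single
#' run they compare the per-read binary indicators. No multiple-comparison
#' correction is applied.
#'
#' @param reports `data.frame` with columns `read_id`, `chimera_type`,
#'   `has_smoothed_segment`, and optionally `run`.
#' @return A list with `fractions` (named per-type, `NA` for absent types),
#'   `counts`, and `tests` (a `data.frame` of pairwise p-values).
#' @export
smoothed_segment_prevalence <- function(reports) {
  types <- c("normal", "inverted_repeat", "cross", "gapped")
  present <- intersect(types, unique(reports$chimera_type))
  fractions <- stats::setNames(rep(NA_real_, length(types)), types)
  counts <- stats::setNames(rep(0L, length(types)), types)
  for (t in present) {
    sel <- reports$chimera_type == t
    counts[t] <- sum(sel)
    fractions[t] <- mean(reports$has_smoothed_segment[sel])
  }
  multi_run <- "run" %in% names(reports) && length(unique(reports$run)) > 1L
  pairs <- utils::combn(present, 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(p) {
    xa <- reports[reports$chimera_type == p[1], , drop = FALSE]
    xb <- reports[reports$chimera_type == p[2], , drop = FALSE]
    va <- if (multi_run) tapply(xa$has_smoothed_segment, xa$run, mean) else
      as.numeric(xa$has_smoothed_segment)
    vb <- if (multi_run) tapply(xb$has_smoothed_segment, xb$run, mean) else
      as.numeric(xb$has_smoothed_segment)
    pv <- tryCatch(
      suppressWarnings(stats::wilcox.test(va, vb, exact = FALSE)$p.value),
      error = function(e) NA_real_)
    if (is.nan(pv)) pv <- 1  # identical constant groups: no evidence of difference
    data.frame(type_a = p[1], type_b = p[2], p_value = pv,
               stringsAsFactors = FALSE)
  }))
  list(fractions = fractions, counts = counts, tests = tests)
}

#' Compute smoothed-segment reports for a set of reads
#'
#' Convenience wrapper joining chimera calls to signals: chimeric reads are
#' scanned at their recorded breakpoint (mapped to a signal index), normal
#' reads at their truth anchor when one is supplied, otherwise at a seeded
#' pseudo-breakpoint.
#'
#' @param signals Named list of [raw_signal()] objects.
#' @param calls Call table from [classify_reads()] (needs `read_id`,
#'   `chimera_type`, `breakpoint`).
#' @param read_lens Named vector of read lengths in bases.
#' @param config A [feature_config()].
#' @param anchors Optional named vector of signal indices overriding the
#'   scan anchor per read (e.g. simulator truth for normal reads).
#' @param seed Seed for normal-read pseudo-breakpoints.
#' @return `data.frame` of per-read reports with `chimera_type` attached.
#' @export
feature_reports <- function(signals, calls, read_lens,
                            config = feature_config(), anchors = NULL,
                            seed = 1L) {
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    id <- calls$read_id[i]
    sig <- signals[[id]]
    if (is.null(sig)) return(NULL)
    bp <- if (!is.null(anchors) && id %in% names(anchors)) {
      as.integer(anchors[[id]])
    } else if (calls$chimera_type[i] != "normal" && !is.na(calls$breakpoint[i])) {
      breakpoint_to_signal_index(sig, calls$breakpoint[i], read_lens[[id]])
    } else {
      pseudo_breakpoint(sig, config, seed)
    }
    rep <- detect_smoothed_segment(sig, bp, config)
    rep$chimera_type <- calls$chimera_type[i]
    rep$bp_index <- bp
    rep
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
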