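#' Preprocessing configuration for classifier inputs
#'
#' Raw traces are turned into fixed-length model inputs by a fixed pipeline:
#' trim the first `head_trim` samples (pre-sequencing noise), slice `N`
#' samples on each side of the breakpoint (2N total; normal reads get a
#' random 2N slice), replace extreme outliers, Z-score, and right-pad with
#' zeros to exactly 2N. The published operating point is `head_trim = 1500`,
#' `half_window_N = 10000` (input length 20,000), outliers defined as
#' samples exceeding three times the average value.
#'
#' @param head_trim Samples trimmed from the trace start.
#' @param half_window_N Half window, samples; input length is `2 * half_window_N`.
#' @param outlier_k Outlier threshold as a multiple of the mean.
#' @param pad_value Value used for right padding (after Z-scoring).
#' @param abs_mean Define outliers on absolute values with the mean of
#'   absolute samples as reference (default); `FALSE` uses the signed mean.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(head_trim = 1500, half_window_N = 10000,
                              outlier_k = 3.0, pad_value = 0.0,
                              abs_mean = TRUE) {
  stopifnot(half_window_N > 0, outlier_k > 1, head_trim >= 0)
  structure(list(head_trim = as.integer(head_trim),
                 half_window_N = as.integer(half_window_N),
                 outlier_k = outlier_k, pad_value = pad_value,
                 abs_mean = abs_mean),
            class = "preprocess_config")
}

#' Replace extreme outliers by neighbour averaging
#'
#' Samples whose magnitude exceeds `k` times the average magnitude of the
#' input are replaced by the mean of their nearest non-outlier neighbours
#' (one on each side; at the boundary, the single available neighbour). All
#' other samples are unchanged and the length is preserved.
#'
#' @param samples Numeric vector.
#' @param k Threshold multiple of the mean (default 3).
#' @param abs_mean Use absolute values for both the reference mean and the
#'   comparison (default); `FALSE` compares raw values against the signed mean.
#' @return Numeric vector of the same length.
#' @export
smooth_outliers <- function(samples, k = 3.0, abs_mean = TRUE) {
  if (!length(samples)) stop("empty vector")
  ref <- if (abs_mean) mean(abs(samples)) else mean(samples)
  is_out <- if (abs_mean) abs(samples) > k * ref else samples > k * ref
  if (!any(is_out)) return(samples)
  if (all(is_out)) stop("all samples are outliers; replacement undefined")
  good <- which(!is_out)
  out <- samples
  for (i in which(is_out)) {
    left <- good[good < i]
    right <- good[good > i]
    nb <- c(if (length(left)) samples[max(left)],
            if (length(right)) samples[min(right)])
    out[i] <- mean(nb)
  }
  out
}

#' Extract a fixed-length breakpoint-centered signal window
#'
#' Pipeline order is fixed: (1) trim the first `head_trim` samples; (2) slice
#' `[bp - N, bp + N)` clipped to the trace (for `bp_index = NULL`, i.e. a
#' normal read, a random 2N slice with a start seeded per read); (3) outlier
#' smoothing; (4) Z-score normalization of the slice; (5) right zero-padding
#' to exactly 2N samples. `bp_index` is an index into the full trace; a
#' breakpoint inside the trimmed head yields a clipped, padded window.
#'
#' @param signal A [raw_signal()].
#' @param bp_index 0-based breakpoint signal index, or `NULL` for a random
#'   slice (normal reads).
#' @param config A [preprocess_config()].
#' @param label Window label, `"fp_chimera"` or `"normal"`.
#' @param seed Integer seed for the normal-read random slice (combined with
#'   the read id, so membership is order-independent).
#' @return A list of class `signal_window`: `read_id`, `values` (length 2N),
#'   `label`, `n_padded`, `source_breakpoint`.
#' @export
extract_window <- function(signal, bp_index = NULL,
                           config = preprocess_config(),
                           label = c("fp_chimera", "normal"), seed = 1L) {
  label <- match.arg(label)
  N <- config$half_window_N
  x <- signal$samples
  if (length(x) <= config$head_trim) {
    stop("trace shorter than the head trim: ", signal$read_id)
  }
  x <- x[(config$head_trim + 1L):length(x)]
  L <- length(x)
  if (is.null(bp_index)) {
    start <- with_seed(as.integer(seed) + id_key(signal$read_id), {
      if (L <= 2L * N) 0L else sample.int(L - 2L * N, 1L) - 1L
    })
    lo <- start
    hi <- min(L, start + 2L * N)
  } else {
    p <- as.integer(bp_index) - config$head_trim   # position in trimmed trace
    lo <- max(0L, p - N)
    hi <- min(L, p + N)
  }
  if (hi <= lo) {
    slice <- numeric(0)
  } else {
    slice <- x[(lo + 1L):hi]
  }
  if (length(slice)) {
    slice <- smooth_outliers(slice, k = config$outlier_k,
                             abs_mean = config$abs_mean)
    s <- stats::sd(slice)
    slice <- if (is.finite(s) && s > 0) (slice - mean(slice)) / s else slice - mean(slice)
  }
  n_pad <- 2L * N - length(slice)
  values <- c(slice, rep(config$pad_value, n_pad))
  structure(list(read_id = signal$read_id, values = values, label = label,
                 n_padded = n_pad,
                 source_breakpoint = if (is.null(bp_index)) NA_integer_ else as.integer(bp_index)),
            class = "signal_window")
}

#' Assemble windows into train/validation/test sets
#'
#' Optionally balances the classes by downsampling normals to the
#' FP-chimera count (seeded), then splits by read, stratified by label, in
#' the given proportions (default 8:1:1). Membership is a deterministic
#' function of read ids and the seed, so permuting the input order changes
#' nothing.
#'
#' @param windows List of `signal_window` objects.
#' @param split Numeric vector of three ratios, default `c(8, 1, 1)`.
#' @param balance Downsample normals to match the FP-chimera count.
#' @param seed Integer seed.
#' @return A list with `train`, `val`, `test`; each holds `x` (matrix, one
#'   window per row), `y` (integer labels, 1 = fp_chimera, 0 = normal) and
#'   `read_id`.
#' @export
build_dataset <- function(windows, split = c(8, 1, 1), balance = TRUE,
                          seed = 1L) {
  stopifnot(length(split) == 3, all(split > 0))
  labels <- vapply(windows, `[[`, "", "label")
  ids <- vapply(windows, `[[`, "", "read_id")
  if (!all(c("fp_chimera", "normal") %in% labels)) {
    stop("both labels must be present to build a dataset")
  }
  ord <- order(ids)  # canonical order: invariant to input permutation
  windows <- windows[ord]; labels <- labels[ord]; ids <- ids[ord]
  ratios <- split / sum(split)
  # Largest-remainder allocation of n items over the three arms; ties go to
  # the arm with the largest global deficit so that, across the two strata,
  # totals track the target proportions within one read.
  alloc_counts <- function(n, global_alloc, global_total) {
    ideal <- n * ratios
    base <- floor(ideal)
    rem <- ideal - base
    left <- n - sum(base)
    while (left > 0) {
      cand <- which(rem >= max(rem) - 1e-12)
      if (length(cand) > 1L) {
        deficit <- (global_total + n) * ratios - (global_alloc + base)
        cand <- cand[which.max(deficit[cand])]
      }
      base[cand[1]] <- base[cand[1]] + 1
      rem[cand[1]] <- -1
      left <- left - 1
    }
    base
  }
  pick <- with_seed(as.integer(seed), local({
    idx_pos <- which(labels == "fp_chimera")
    idx_neg <- which(labels == "normal")
    if (balance && length(idx_neg) > length(idx_pos)) {
      idx_neg <- sort(sample(idx_neg, length(idx_pos)))
    }
    global_alloc <- c(0, 0, 0)
    global_total <- 0
    assign_split <- function(idx) {
      idx <- sample(idx)  # seeded shuffle
      n <- length(idx)
      cnt <- alloc_counts(n, global_alloc, global_total)
      global_alloc <<- global_alloc + cnt
      global_total <<- global_total + n
      list(train = idx[seq_len(cnt[1])],
           val = idx[cnt[1] + seq_len(cnt[2])],
           test = idx[cnt[1] + cnt[2] + seq_len(cnt[3])])
    }
    p <- assign_split(idx_pos)
    q <- assign_split(idx_neg)
    list(train = c(p$train, q$train), val = c(p$val, q$val),
         test = c(p$test, q$test))
  }))
  take <- function(idx) {
    idx <- sort(idx)
    list(x = do.call(rbind, lapply(windows[idx], `[[`, "values")),
         y = as.integer(labels[idx] == "fp_chimera"),
         read_id = ids[idx])
  }
  list(train = take(pick$train), val = take(pick$val), test = take(pick$test))
}
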