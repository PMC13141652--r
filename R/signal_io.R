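#' Raw current trace container
#'
#' A light S3 record for one read's raw nanopore current trace: the digitized
#' samples, an optional monotone base-index-to-signal-index map (as produced
#' by a resquiggler or by the built-in simulator), and the source tag.
#'
#' @param read_id Read identifier.
#' @param samples Numeric vector of current values (digitized units or pA).
#' @param base_to_signal Optional non-decreasing integer vector, one entry
#'   per read base, giving the 0-based signal index where that base starts.
#' @param source One of `"signal_table"`, `"simulated"`.
#' @return An object of class `raw_signal`.
#' @export
raw_signal <- function(read_id, samples,
                       base_to_signal = NULL,
                       source = "signal_table") {
  samples <- as.numeric(samples)
  if (!length(samples)) stop("empty signal for read ", read_id)
  if (!is.null(base_to_signal)) {
    base_to_signal <- as.integer(base_to_signal)
    if (is.unsorted(base_to_signal)) stop("base_to_signal must be non-decreasing")
    if (min(base_to_signal) < 0L || max(base_to_signal) >= length(samples)) {
      stop("base_to_signal indices outside the trace")
    }
  }
  structure(list(read_id = read_id, samples = samples,
                 sample_count = length(samples),
                 base_to_signal = base_to_signal, source = source),
            class = "raw_signal")
}

#' @export
print.raw_signal <- function(x, ...) {
  cat(sprintf("<raw_signal %s: %d samples%s, source=%s>\n", x$read_id,
              x$sample_count,
              if (is.null(x$base_to_signal)) "" else ", base map",
              x$source))
  invisible(x)
}

#' Read raw signals from a signal table
#'
#' The signal table is a plain tab-separated text format with one read per
#' line and no header: column 1 the read id, column 2 the comma-separated
#' current samples, and an optional column 3 with the comma-separated
#' base-to-signal map (one 0-based signal index per read base). It is the
#' on-disk raw-signal format written by the simulator and accepted
#' everywhere a FAST5 archive would otherwise be used.
#'
#' @param path Path to the signal table (optionally gzip-compressed).
#' @param format Only `"signal_table"` is supported; `"fast5"` aborts with an
#'   explanatory error (HDF5 input is not handled by this package).
#' @return A named list of [raw_signal()] objects (names = read ids).
#' @export
read_signals <- function(path, format = c("signal_table", "fast5")) {
  format <- match.arg(format)
  if (format == "fast5") {
    stop("FAST5/HDF5 input is not supported; convert to the signal-table ",
         "format (read_id<TAB>comma-separated samples[<TAB>base map])")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  if (!length(lines)) return(stats::setNames(list(), character()))
  out <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L) stop("malformed signal-table line ", i)
    map <- if (length(f) >= 3L && nzchar(f[3])) {
      as.integer(strsplit(f[3], ",", fixed = TRUE)[[1]])
    } else NULL
    raw_signal(f[1], as.numeric(strsplit(f[2], ",", fixed = TRUE)[[1]]),
               base_to_signal = map, source = "signal_table")
  })
  stats::setNames(out, vapply(out, `[[`, "", "read_id"))
}

#' Write raw signals to a signal table
#'
#' @param signals A list of [raw_signal()] objects.
#' @param path Output path (gzip-compressed if it ends in `.gz`).
#' @param digits Significant digits kept for the samples.
#' @return `path`, invisibly.
#' @export
write_signals <- function(signals, path, digits = 6) {
  lines <- vapply(signals, function(s) {
    v <- paste(formatC(s$samples, digits = digits, format = "g"), collapse = ",")
    m <- if (is.null(s$base_to_signal)) "" else
      paste0("\t", paste(s$base_to_signal, collapse = ","))
    paste0(s$read_id, "\t", v, m)
  }, character(1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  writeLines(lines, con)
  close(con)
  invisible(path)
}

#' Map a read-base breakpoint to a signal index
#'
#' Uses the base-to-signal map when the trace carries one (resquiggled or
#' simulated); otherwise falls back to proportional interpolation,
#' `floor(breakpoint / read_len * sample_count)`.
#'
#' @param signal A [raw_signal()].
#' @param breakpoint_read_pos Base offset of the junction on the read, in
#'   `[0, read_len]`.
#' @param read_len Read length in bases.
#' @return 0-based signal index.
#' @export
breakpoint_to_signal_index <- function(signal, breakpoint_read_pos, read_len) {
  stopifnot(breakpoint_read_pos >= 0, breakpoint_read_pos <= read_len)
  if (!is.null(signal$base_to_signal)) {
    m <- signal$base_to_signal
    i <- min(length(m), as.integer(breakpoint_read_pos) + 1L)
    if (i < 1L) i <- 1L
    return(m[i])
  }
  idx <- floor(breakpoint_read_pos / read_len * signal$sample_count)
  as.integer(min(idx, signal$sample_count - 1L))
}
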