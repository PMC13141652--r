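#' Read long-read alignments into a per-fragment table
#'
#' Parses PAF or SAM/BAM alignments of long reads against a reference and
#' normalizes them into one row per aligned read fragment, the unit used by
#' downstream chimera typing. Coordinates are 0-based half-open on both the
#' read and the reference regardless of the source format (PAF-native
#' convention; SAM's 1-based inclusive coordinates are converted on ingest).
#' Secondary alignments (SAM flag 0x100, PAF `tp:A:S`) are dropped: the
#' high-MapQ filter applied downstream is only meaningful for primary and
#' supplementary records.
#'
#' For SAM records, read-side coordinates are reconstructed from the CIGAR
#' string: the full read length is the sum of query-consuming operations plus
#' hard clips, and the aligned interval is delimited by leading/trailing
#' clips. For minus-strand alignments the clip roles are swapped so that
#' `q_start`/`q_end` always refer to the original read orientation, as in PAF.
#'
#' @param path Path to a `.paf`, `.sam` or `.bam` file.
#' @param format Input format; inferred from the file extension by default.
#' @param on_error `"skip"` drops malformed lines with a warning naming the
#'   line number; `"abort"` stops on the first malformed line.
#' @return A `data.frame` with columns `read_id`, `read_len`, `q_start`,
#'   `q_end`, `strand`, `target`, `t_start`, `t_end`, `mapq`,
#'   `is_supplementary`. One row per retained fragment.
#' @examples
#' paf <- tempfile(fileext = ".paf")
#' writeLines("r1\t1500\t0\t700\t+\tchr1\t10000\t100\t800\t650\t700\t60", paf)
#' read_alignments(paf)
#' @export
read_alignments <- function(path,
                            format = c("auto", "paf", "sam", "bam"),
                            on_error = c("skip", "abort")) {
  format <- match.arg(format)
  on_error <- match.arg(on_error)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, paf = "paf", sam = "sam", bam = "bam",
                     stop("cannot infer alignment format from extension: ", path))
  }
  frags <- switch(format,
    paf = parse_paf(path, on_error),
    sam = parse_sam_bam(path, binary = FALSE, on_error = on_error),
    bam = parse_sam_bam(path, binary = TRUE, on_error = on_error)
  )
  validate_fragments(frags)
  frags
}

empty_fragments <- function() {
  data.frame(read_id = character(), read_len = integer(),
             q_start = integer(), q_end = integer(), strand = character(),
             target = character(), t_start = integer(), t_end = integer(),
             mapq = integer(), is_supplementary = logical(),
             stringsAsFactors = FALSE)
}

parse_paf <- function(path, on_error) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(empty_fragments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) < 12L)
  if (length(bad)) {
    msg <- sprintf("malformed PAF line(s): %s", paste(bad, collapse = ", "))
    if (on_error == "abort") stop(msg)
    warning(msg, "; skipped")
    fields <- fields[-bad]
    if (!length(fields)) return(empty_fragments())
  }
  core <- t(vapply(fields, function(f) f[1:12], character(12)))
  # tp:A tag: P = primary, S = secondary (dropped), I/i = inversion-aware
  # primaries from some aligners; absence is treated as primary.
  tp <- vapply(fields, function(f) {
    tag <- grep("^tp:A:", f[-(1:12)], value = TRUE)
    if (length(tag)) substr(tag[1], 6, 6) else "P"
  }, character(1))
  num <- function(j) suppressWarnings(as.integer(core[, j]))
  frags <- data.frame(
    read_id = core[, 1], read_len = num(2), q_start = num(3), q_end = num(4),
    strand = core[, 5], target = core[, 6], t_start = num(8), t_end = num(9),
    mapq = num(12),
    is_supplementary = FALSE,
    stringsAsFactors = FALSE
  )
  # PAF has no supplementary flag; convention: the primary carries tp:A:P,
  # additional alignments of the same read either carry tp:A:S (secondary,
  # dropped) or are supplementary primaries. An explicit supp:i tag (written
  # by write_paf) takes precedence; otherwise every record after the first
  # for a read is treated as supplementary.
  supp_tag <- vapply(fields, function(f) {
    tag <- grep("^supp:i:", f[-(1:12)], value = TRUE)
    if (length(tag)) as.integer(substr(tag[1], 8, nchar(tag[1]))) else NA_integer_
  }, integer(1))
  keep <- tp != "S"
  frags <- frags[keep, , drop = FALSE]
  supp_tag <- supp_tag[keep]
  bad_num <- which(is.na(frags$read_len) | is.na(frags$q_start) |
                     is.na(frags$q_end) | is.na(frags$mapq))
  if (length(bad_num)) {
    msg <- sprintf("non-numeric PAF coordinate field(s) on %d line(s)", length(bad_num))
    if (on_error == "abort") stop(msg)
    warning(msg, "; skipped")
    frags <- frags[-bad_num, , drop = FALSE]
    supp_tag <- supp_tag[-bad_num]
  }
  if (nrow(frags)) {
    known <- !is.na(supp_tag)
    frags$is_supplementary[known] <- supp_tag[known] == 1L
    if (any(!known)) {
      first <- !duplicated(frags$read_id)
      frags$is_supplementary[!known] <- !first[!known]
    }
  }
  rownames(frags) <- NULL
  frags
}

#' @importFrom Rsamtools scanBam ScanBamParam scanBamFlag asBam
parse_sam_bam <- function(path, binary, on_error) {
  bam <- if (binary) path else {
    tmp <- tempfile(fileext = ".bam")
    Rsamtools::asBam(path, sub("\\.bam$", "", tmp), overwrite = TRUE,
                     indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE)
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(res$qname)
  if (n == 0L) return(empty_fragments())
  cig <- parse_cigar_batch(res$cigar)
  minus <- bitwAnd(res$flag, 16L) > 0L
  q_start <- ifelse(minus, cig$clip_right, cig$clip_left)
  q_end <- ifelse(minus, cig$read_len - cig$clip_left, cig$read_len - cig$clip_right)
  frags <- data.frame(
    read_id = res$qname,
    read_len = cig$read_len,
    q_start = q_start, q_end = q_end,
    strand = ifelse(minus, "-", "+"),
    target = as.character(res$rname),
    t_start = res$pos - 1L,                      # SAM 1-based -> 0-based
    t_end = res$pos - 1L + cig$ref_len,
    mapq = as.integer(res$mapq),
    is_supplementary = bitwAnd(res$flag, 2048L) > 0L,
    stringsAsFactors = FALSE
  )
  bad <- which(frags$q_start >= frags$q_end | cig$ref_len <= 0L)
  if (length(bad)) {
    msg <- sprintf("%d SAM record(s) with empty aligned span", length(bad))
    if (on_error == "abort") stop(msg)
    warning(msg, "; skipped")
    frags <- frags[-bad, , drop = FALSE]
  }
  rownames(frags) <- NULL
  frags
}

# CIGAR arithmetic: read_len = sum of query-consuming ops (M/I/S/=/X) plus
# hard clips; ref_len = sum of reference-consuming ops (M/D/N/=/X); clips in
# SAM orientation.
parse_cigar_batch <- function(cigars) {
  ops <- regmatches(cigars, gregexpr("\\d+[MIDNSHP=X]", cigars))
  one <- function(o) {
    len <- as.integer(sub("[MIDNSHP=X]", "", o))
    op <- substr(o, nchar(o), nchar(o))
    q <- sum(len[op %in% c("M", "I", "S", "=", "X")])
    h <- sum(len[op == "H"])
    r <- sum(len[op %in% c("M", "D", "N", "=", "X")])
    nlead <- 0L
    i <- 1L
    while (i <= length(op) && op[i] %in% c("S", "H")) { nlead <- nlead + len[i]; i <- i + 1L }
    ntrail <- 0L
    i <- length(op)
    while (i >= 1L && op[i] %in% c("S", "H")) { ntrail <- ntrail + len[i]; i <- i - 1L }
    c(q + h, r, nlead, ntrail)
  }
  m <- vapply(ops, one, numeric(4))
  list(read_len = as.integer(m[1, ]), ref_len = as.integer(m[2, ]),
       clip_left = as.integer(m[3, ]), clip_right = as.integer(m[4, ]))
}

validate_fragments <- function(frags) {
  if (!nrow(frags)) return(invisible(frags))
  ok <- frags$q_start >= 0 & frags$q_start < frags$q_end &
    frags$q_end <= frags$read_len & frags$t_start >= 0 &
    frags$t_start < frags$t_end
  if (!all(ok)) {
    stop("invalid alignment record(s) at row(s): ",
         paste(utils::head(which(!ok), 5), collapse = ", "))
  }
  invisible(frags)
}

#' Filter alignment fragments by mapping quality
#'
#' Drops fragments below a MapQ cutoff. With `per_read = TRUE` an entire read
#' is discarded if any of its fragments falls below the cutoff, a stricter
#' reading of the same rule; the default filters fragment-wise.
#'
#' @param frags Fragment table from [read_alignments()].
#' @param min_mapq Minimum mapping quality retained (default 60, the maximum
#'   minimap2 reports; this removes multi-mapping ambiguity).
#' @param per_read Apply the cutoff per read instead of per fragment.
#' @return The filtered fragment table, input order preserved.
#' @export
filter_mapq <- function(frags, min_mapq = 60, per_read = FALSE) {
  stopifnot(min_mapq >= 0, min_mapq <= 60)
  if (!nrow(frags)) return(frags)
  if (per_read) {
    bad_reads <- unique(frags$read_id[frags$mapq < min_mapq])
    out <- frags[!(frags$read_id %in% bad_reads), , drop = FALSE]
  } else {
    out <- frags[frags$mapq >= min_mapq, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Group fragments by read and flag chimera candidates
#'
#' Orders each read's fragments by their start position on the read and
#' reports which reads are split-alignment chimera candidates: at least two
#' fragments, at least one of them supplementary.
#'
#' @param frags Fragment table from [read_alignments()].
#' @return A list with `fragments` (the table, sorted by read then `q_start`)
#'   and `reads`, a `data.frame` with one row per read (`read_id`,
#'   `read_len`, `n_fragments`, `candidate`).
#' @export
group_by_read <- function(frags) {
  if (nrow(frags)) {
    len_chk <- tapply(frags$read_len, frags$read_id, function(x) length(unique(x)))
    if (any(len_chk > 1L)) {
      stop("conflicting read_len for read(s): ",
           paste(names(len_chk)[len_chk > 1L], collapse = ", "))
    }
  }
  ord <- order(frags$read_id, frags$q_start)
  frags <- frags[ord, , drop = FALSE]
  rownames(frags) <- NULL
  if (!nrow(frags)) {
    reads <- data.frame(read_id = character(), read_len = integer(),
                        n_fragments = integer(), candidate = logical(),
                        stringsAsFactors = FALSE)
    return(list(fragments = frags, reads = reads))
  }
  dt <- data.table::as.data.table(frags)
  rd <- dt[, list(read_len = read_len[1L], n_fragments = .N,
                  candidate = .N >= 2L && any(is_supplementary)),
           by = "read_id"]
  list(fragments = frags, reads = as.data.frame(rd))
}

#' Write a fragment table as PAF
#'
#' Emits one PAF line per fragment with `tp:A:P` on primaries and a
#' `supp:i:1` tag on supplementaries so that [read_alignments()] round-trips
#' the supplementary flag. Residue-match and block-length columns are filled
#' with the read-side span.
#'
#' @param frags Fragment table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(frags, path) {
  span <- frags$q_end - frags$q_start
  # column 7 is target length; we do not track it, so emit t_end as a lower
  # bound (valid PAF requires t_len >= t_end)
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\ttp:A:P\tsupp:i:%d",
                   frags$read_id, frags$read_len, frags$q_start, frags$q_end,
                   frags$strand, frags$target, frags$t_end,
                   frags$t_start, frags$t_end, span, span, frags$mapq,
                   as.integer(frags$is_supplementary))
  writeLines(lines, path)
  invisible(path)
}

#' Write the fragment table as TSV
#'
#' Plain tab-separated dump with a header, the interchange format consumed by
#' the detection and feature stages of the command-line pipeline.
#'
#' @param frags Fragment table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments_tsv <- function(frags, path) {
  utils::write.table(frags, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments_tsv
#' @export
read_fragments_tsv <- function(path) {
  frags <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE,
                             colClasses = c(read_id = "character", target = "character"))
  validate_fragments(frags)
  frags
}
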