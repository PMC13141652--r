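#' Read structural variants from a VCF
#'
#' Extracts one record per VCF line with the `SVTYPE`/`SVLEN` INFO keys.
#' Plain and bgzip/gzip-compressed files are handled identically. Records
#' without `SVTYPE` are skipped with a warning; deletion lengths keep the
#' conventional negative `SVLEN` sign but are reported as absolute sizes in
#' `svlen`.
#'
#' @param path Path to a `.vcf` or `.vcf.gz` file.
#' @param pass_only Keep only records whose FILTER is `PASS` or `.`.
#' @return `data.frame` with `chrom`, `pos` (1-based), `id`, `svtype`,
#'   `svlen` (absolute size in bp, `NA` when absent).
#' @export
read_vcf_svs <- function(path, pass_only = FALSE) {
  v <- suppressMessages(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) {
    return(data.frame(chrom = character(), pos = integer(), id = character(),
                      svtype = character(), svlen = numeric(),
                      stringsAsFactors = FALSE))
  }
  svtype <- vapply(fix$INFO, function(s) {
    m <- regmatches(s, regexpr("(?:^|;)SVTYPE=([^;]+)", s, perl = TRUE))
    if (length(m)) sub(".*SVTYPE=", "", m) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  svlen <- vapply(fix$INFO, function(s) {
    m <- regmatches(s, regexpr("(?:^|;)SVLEN=(-?[0-9]+)", s, perl = TRUE))
    if (length(m)) as.numeric(sub(".*SVLEN=", "", m)) else NA_real_
  }, numeric(1), USE.NAMES = FALSE)
  keep <- !is.na(svtype)
  if (any(!keep)) warning(sum(!keep), " record(s) without SVTYPE skipped")
  if (pass_only) keep <- keep & fix$FILTER %in% c("PASS", ".", NA)
  out <- data.frame(chrom = fix$CHROM[keep],
                    pos = as.integer(fix$POS[keep]),
                    id = fix$ID[keep],
                    svtype = svtype[keep],
                    svlen = abs(svlen[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Compare a clean and a raw SV call set
#'
#' Two SVs match iff they share chromosome and type, their positions differ
#' by at most `match_tolerance` bp, and — when both have a defined size —
#' the smaller/larger size ratio is at least `min_size_ratio`. Matching is
#' greedy one-to-one by position distance. The error rate attributes to the
#' raw set the calls absent from the clean set (FP) and, by default, also
#' the clean calls the raw set missed (FN):
#' `error_rate = (FP + FN) / max(n_clean, 1)`.
#'
#' @param clean SV table of the filtered (truth-side) call set.
#' @param raw SV table of the unfiltered call set.
#' @param match_tolerance Maximum position difference in bp (default 500).
#' @param min_size_ratio Minimum size ratio between matched SVs (default 0.7).
#' @param include_fn Include FN in the numerator (default `TRUE`); `FALSE`
#'   counts only FP over true SVs.
#' @return A list: `fp`, `fn` (data frames of unmatched records), `n_clean`,
#'   `n_raw`, `n_matched`, `error_rate`, `denominator_guarded` (`TRUE` when
#'   the clean set was empty and the denominator fell back to 1).
#' @export
compare_sv_sets <- function(clean, raw, match_tolerance = 500,
                            min_size_ratio = 0.7, include_fn = TRUE) {
  match_pairs <- function(a, b) {
    used_b <- rep(FALSE, nrow(b))
    match_a <- rep(NA_integer_, nrow(a))
    for (i in seq_len(nrow(a))) {
      cand <- which(!used_b & b$chrom == a$chrom[i] & b$svtype == a$svtype[i] &
                      abs(b$pos - a$pos[i]) <= match_tolerance)
      if (!length(cand)) next
      ok <- vapply(cand, function(j) {
        if (is.na(a$svlen[i]) || is.na(b$svlen[j])) return(TRUE)
        lo <- min(a$svlen[i], b$svlen[j]); hi <- max(a$svlen[i], b$svlen[j])
        hi == 0 || lo / hi >= min_size_ratio
      }, logical(1))
      cand <- cand[ok]
      if (!length(cand)) next
      j <- cand[which.min(abs(b$pos[cand] - a$pos[i]))]
      match_a[i] <- j
      used_b[j] <- TRUE
    }
    list(match_a = match_a, used_b = used_b)
  }
  m <- match_pairs(clean, raw)
  fn <- clean[is.na(m$match_a), , drop = FALSE]
  fp <- raw[!m$used_b, , drop = FALSE]
  guarded <- nrow(clean) == 0
  denom <- max(nrow(clean), 1)
  num <- nrow(fp) + if (include_fn) nrow(fn) else 0
  list(fp = fp, fn = fn, n_clean = nrow(clean), n_raw = nrow(raw),
       n_matched = sum(!is.na(m$match_a)), error_rate = num / denom,
       denominator_guarded = guarded)
}

#' Random read-removal control set
#'
#' Removes `n_remove` read ids uniformly at random without replacement,
#' mirroring the dose-matched control arm: the same number of reads is
#' removed as the classifier filtered, but chosen blindly.
#'
#' @param read_ids Character vector of read ids in the raw set.
#' @param n_remove Number of reads to remove.
#' @param seed Integer seed.
#' @return A list with `kept_ids` and `removed_ids`.
#' @export
make_control <- function(read_ids, n_remove, seed = 1L) {
  if (n_remove > length(read_ids)) stop("n_remove exceeds the read count")
  removed <- with_seed(seed, {
    if (n_remove == 0) character() else sample(read_ids, n_remove)
  })
  list(kept_ids = setdiff(read_ids, removed), removed_ids = removed)
}

#' Write a minimal SV VCF
#'
#' Emits a small VCFv4.2 file with `SVTYPE`/`SVLEN`/`END` INFO keys, used
#' for fixtures and by the built-in toy caller. Deletions get negative
#' `SVLEN` per convention.
#'
#' @param svs SV table (`chrom`, `pos`, `svtype`, `svlen`, optional `id`).
#' @param path Output path (gzip-compressed if it ends in `.gz`).
#' @param contigs Optional named vector of contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(svs, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=nanochimera",
           '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
           '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
           '##INFO=<ID=END,Number=1,Type=Integer,Description="SV end">',
           '##ALT=<ID=DEL,Description="Deletion">',
           '##ALT=<ID=INS,Description="Insertion">',
           '##ALT=<ID=INV,Description="Inversion">')
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(svs)) {
    id <- if ("id" %in% names(svs)) svs$id else sprintf("sv%d", seq_len(nrow(svs)))
    len <- ifelse(is.na(svs$svlen), 0L, as.integer(svs$svlen))
    signed <- ifelse(svs$svtype == "DEL", -len, len)
    end <- as.integer(svs$pos) + ifelse(svs$svtype %in% c("DEL", "INV", "DUP"), len, 0L)
    sprintf("%s\t%d\t%s\tN\t<%s>\t.\tPASS\tSVTYPE=%s;SVLEN=%d;END=%d",
            svs$chrom, as.integer(svs$pos), id, svs$svtype, svs$svtype,
            signed, end)
  } else character()
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  writeLines(c(hdr, body), con)
  close(con)
  invisible(path)
}

#' Naive split-read SV caller (simulation adapter)
#'
#' A deliberately simple mosaic SV caller over the package's fragment
#' tables, provided so the evaluation stage can run end-to-end on simulated
#' data without an external caller. Reads whose two fragments imply a
#' junction (same-chromosome gap => DEL, opposite strands => INV, two
#' chromosomes => BND) are clustered by junction position; a cluster becomes
#' a call when it has at least `min_support` reads and its supporting-read
#' fraction of all reads is at least `af_min` (the mosaic allele-frequency
#' floor). It is an adapter for testing the comparison machinery, not a
#' reimplementation of a production caller.
#'
#' @param frags Fragment table (already grouped/filtered).
#' @param read_ids Read ids present in the dataset arm (defines the AF
#'   denominator and which fragments are used).
#' @param min_support Minimum supporting reads per call.
#' @param af_min Minimum support fraction of all reads.
#' @param min_gap Minimum same-chromosome reference gap treated as a DEL
#'   junction, bp.
#' @param cluster_window Junction clustering width, bp.
#' @return SV table (`chrom`, `pos`, `svtype`, `svlen`, `support`, `af`).
#' @export
call_svs_from_fragments <- function(frags, read_ids = unique(frags$read_id),
                                    min_support = 3, af_min = 0.02,
                                    min_gap = 50, cluster_window = 500) {
  frags <- frags[frags$read_id %in% read_ids, , drop = FALSE]
  n_reads <- length(unique(read_ids))
  pieces <- split(frags, frags$read_id)
  jx <- do.call(rbind, lapply(pieces, function(fr) {
    if (nrow(fr) < 2L) return(NULL)
    fr <- fr[order(fr$q_start), , drop = FALSE]
    a <- fr[1, ]; b <- fr[2, ]
    if (a$target != b$target) {
      return(data.frame(chrom = a$target, pos = a$t_end, svtype = "BND",
                        svlen = NA_real_, stringsAsFactors = FALSE))
    }
    if (a$strand != b$strand) {
      lo <- min(a$t_start, b$t_start); hi <- max(a$t_end, b$t_end)
      return(data.frame(chrom = a$target, pos = as.numeric(lo), svtype = "INV",
                        svlen = as.numeric(hi - lo), stringsAsFactors = FALSE))
    }
    gap <- max(a$t_start, b$t_start) - min(a$t_end, b$t_end)
    if (gap >= min_gap) {
      return(data.frame(chrom = a$target, pos = as.numeric(min(a$t_end, b$t_end)),
                        svtype = "DEL", svlen = as.numeric(gap),
                        stringsAsFactors = FALSE))
    }
    NULL
  }))
  empty <- data.frame(chrom = character(), pos = integer(), svtype = character(),
                      svlen = numeric(), support = integer(), af = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(jx) || !nrow(jx)) return(empty)
  calls <- list()
  for (key in unique(paste(jx$chrom, jx$svtype))) {
    sub <- jx[paste(jx$chrom, jx$svtype) == key, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    cl <- cumsum(c(1, diff(sub$pos) > cluster_window))
    for (g in unique(cl)) {
      s <- sub[cl == g, , drop = FALSE]
      if (nrow(s) < min_support) next
      af <- nrow(s) / max(n_reads, 1)
      if (af < af_min) next
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = s$chrom[1], pos = as.integer(round(stats::median(s$pos))),
        svtype = s$svtype[1],
        svlen = if (all(is.na(s$svlen))) NA_real_ else stats::median(s$svlen, na.rm = TRUE),
        support = nrow(s), af = af, stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) return(empty)
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Mosaic allele-frequency gradient scan
#'
#' Recomputes the raw-arm, filtered-arm and control-arm error rates against
#' the clean call set over a range of mosaic AF floors, mirroring a
#' `--mosaic-af-min` gradient test. Arms are defined by their read-id sets;
#' the supplied caller adapter is invoked per arm and AF value.
#'
#' @param frags Fragment table covering all reads.
#' @param arms Named list of read-id vectors; must contain `clean` plus any
#'   arms to compare (typically `raw`, `filtered`, `control`).
#' @param af_values AF floors to scan (default `seq(0.01, 0.08, by = 0.01)`).
#' @param caller Caller adapter `function(frags, read_ids, af_min)` returning
#'   an SV table; defaults to [call_svs_from_fragments()].
#' @param ... Passed to [compare_sv_sets()].
#' @return `data.frame` with `af_min`, `arm`, `n_calls`, `error_rate`.
#' @export
mosaic_gradient_scan <- function(frags, arms,
                                 af_values = seq(0.01, 0.08, by = 0.01),
                                 caller = NULL, ...) {
  stopifnot("clean" %in% names(arms))
  if (is.null(caller)) {
    caller <- function(frags, read_ids, af_min) {
      call_svs_from_fragments(frags, read_ids, af_min = af_min)
    }
  }
  others <- setdiff(names(arms), "clean")
  rows <- list()
  for (af in af_values) {
    clean_calls <- tryCatch(caller(frags, arms$clean, af), error = function(e) NULL)
    for (arm in others) {
      arm_calls <- tryCatch(caller(frags, arms[[arm]], af), error = function(e) NULL)
      if (is.null(clean_calls) || is.null(arm_calls)) {
        rows[[length(rows) + 1L]] <- data.frame(
          af_min = af, arm = arm, n_calls = NA_integer_,
          error_rate = NA_real_, stringsAsFactors = FALSE)
        next
      }
      cmp <- compare_sv_sets(clean_calls, arm_calls, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        af_min = af, arm = arm, n_calls = nrow(arm_calls),
        error_rate = cmp$error_rate, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
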