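sv_row <- function(chrom = "chr1", pos = 1000L, svtype = "DEL",
                   svlen = 709, id = "sv1") {
  data.frame(chrom = chrom, pos = as.integer(pos), id = id, svtype = svtype,
             svlen = svlen, stringsAsFactors = FALSE)
}

test_that("SV VCFs round-trip through plain and gzip encodings", {
  svs <- rbind(sv_row(), sv_row(pos = 5000, svtype = "INS", svlen = 114, id = "sv2"))
  plain <- withr::local_tempfile(fileext = ".vcf")
  gz <- withr::local_tempfile(fileext = ".vcf.gz")
  write_sv_vcf(svs, plain, contigs = c(chr1 = 100000L))
  write_sv_vcf(svs, gz, contigs = c(chr1 = 100000L))
  a <- read_vcf_svs(plain)
  b <- read_vcf_svs(gz)
  expect_equal(a, b)
  expect_equal(nrow(a), 2L)
  # deletion written with negative SVLEN reads back as a 709 bp DEL
  expect_equal(a$svtype[1], "DEL")
  expect_equal(a$svlen[1], 709)
  raw_line <- grep("^chr1\t1000", readLines(plain), value = TRUE)
  expect_match(raw_line, "SVLEN=-709")
})

test_that("records without SVTYPE are skipped with a warning", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="t">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\ta\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;SVLEN=-50",
               "chr1\t200\tb\tN\tT\t.\tPASS\tDP=10"), path)
  expect_warning(svs <- read_vcf_svs(path), "SVTYPE")
  expect_equal(nrow(svs), 1L)
})

test_that("clean-vs-raw comparison reproduces the worked error rates", {
  clean <- rbind(sv_row(), sv_row(pos = 40000, svtype = "INS", svlen = 508, id = "sv2"))
  # raw = clean + one extra unmatched call -> error rate 50%
  raw <- rbind(clean, sv_row(chrom = "chr2", pos = 700, id = "extra"))
  cmp <- compare_sv_sets(clean, raw)
  expect_equal(nrow(cmp$fp), 1L)
  expect_equal(nrow(cmp$fn), 0L)
  expect_equal(cmp$error_rate, 0.5)
  # identical sets
  expect_equal(compare_sv_sets(clean, clean)$error_rate, 0)
  # 4 clean, raw misses one and adds one -> (1+1)/4 = 0.5
  clean4 <- rbind(clean, sv_row(pos = 60000, id = "sv3"),
                  sv_row(pos = 80000, id = "sv4"))
  raw4 <- rbind(clean4[1:3, ], sv_row(chrom = "chr3", pos = 10, id = "x"))
  cmp4 <- compare_sv_sets(clean4, raw4)
  expect_equal(nrow(cmp4$fp), 1L)
  expect_equal(nrow(cmp4$fn), 1L)
  expect_equal(cmp4$error_rate, 0.5)
  # FP-only definition
  expect_equal(compare_sv_sets(clean4, raw4, include_fn = FALSE)$error_rate, 0.25)
})

test_that("matching respects tolerance, type and size ratio", {
  clean <- sv_row(pos = 1000, svlen = 500)
  # within 500 bp and similar size: matched
  expect_equal(compare_sv_sets(clean, sv_row(pos = 1400, svlen = 450))$error_rate, 0)
  # position off by more than the tolerance
  expect_equal(compare_sv_sets(clean, sv_row(pos = 1600, svlen = 500))$error_rate, 2)
  # same position, wrong type
  expect_equal(compare_sv_sets(clean, sv_row(svtype = "INS", svlen = 500))$error_rate, 2)
  # size ratio below 0.7
  expect_equal(compare_sv_sets(clean, sv_row(svlen = 100))$error_rate, 2)
  # swapping the arguments swaps FP and FN
  raw <- rbind(clean, sv_row(chrom = "chr2", id = "y"))
  fwd <- compare_sv_sets(clean, raw)
  rev <- compare_sv_sets(raw, clean)
  expect_equal(nrow(fwd$fp), nrow(rev$fn))
  expect_equal(nrow(fwd$fn), nrow(rev$fp))
  # record order does not matter
  expect_equal(compare_sv_sets(clean[nrow(clean):1, , drop = FALSE],
                               raw[nrow(raw):1, , drop = FALSE])$error_rate,
               fwd$error_rate)
  # empty clean set guards the denominator and flags it
  guard <- compare_sv_sets(clean[0, ], raw)
  expect_true(guard$denominator_guarded)
  expect_equal(guard$error_rate, 2)
})

test_that("adding unmatched raw records never decreases the error rate", {
  set.seed(33)
  clean <- do.call(rbind, lapply(1:5, function(i) {
    sv_row(pos = i * 10000, svlen = 200 + i * 10, id = paste0("c", i))
  }))
  raw <- clean
  last <- compare_sv_sets(clean, raw)$error_rate
  for (i in 1:5) {
    raw <- rbind(raw, sv_row(chrom = "chr9", pos = i * 5000, id = paste0("e", i)))
    now <- compare_sv_sets(clean, raw)$error_rate
    expect_gte(now, last)
    last <- now
  }
})

test_that("control sets remove exactly n reads, reproducibly", {
  ids <- sprintf("r%03d", 1:50)
  expect_equal(make_control(ids, 0, seed = 1)$kept_ids, ids)
  expect_length(make_control(ids, 50, seed = 1)$kept_ids, 0L)
  c1 <- make_control(ids, 10, seed = 7)
  c2 <- make_control(ids, 10, seed = 7)
  expect_identical(c1$removed_ids, c2$removed_ids)
  expect_length(c1$kept_ids, 40L)
  expect_error(make_control(ids, 51), "exceeds")
})

test_that("the naive split-read caller clusters junctions into calls", {
  # six reads supporting one deletion junction, three supporting an inversion
  frs <- list()
  for (i in 1:6) {
    frs[[length(frs) + 1]] <- rbind(
      frag_row(read_id = paste0("d", i), q_end = 700, t_start = 1000 + i,
               t_end = 1700 + i),
      frag_row(read_id = paste0("d", i), q_start = 750, q_end = 1400,
               t_start = 2500 + i, t_end = 3150 + i, is_supplementary = TRUE))
  }
  for (i in 1:3) {
    frs[[length(frs) + 1]] <- chimera_frags("inverted_repeat")
    frs[[length(frs)]]$read_id <- paste0("v", i)
  }
  frags <- do.call(rbind, frs)
  calls <- call_svs_from_fragments(frags, min_support = 3, af_min = 0.01)
  expect_equal(sort(calls$svtype), c("DEL", "INV"))
  del <- calls[calls$svtype == "DEL", ]
  expect_equal(del$support, 6L)
  expect_lt(abs(del$svlen - 800), 20)
  # raising the AF floor above 3/9 silences the inversion
  calls2 <- call_svs_from_fragments(frags, min_support = 3, af_min = 0.5)
  expect_equal(nrow(calls2), 1L)
  expect_equal(calls2$svtype, "DEL")
})

test_that("the mosaic gradient scan tabulates error rates per arm and AF", {
  frags <- do.call(rbind, lapply(1:6, function(i) {
    rbind(frag_row(read_id = paste0("d", i), q_end = 700, t_start = 1000,
                   t_end = 1700),
          frag_row(read_id = paste0("d", i), q_start = 750, q_end = 1400,
                   t_start = 2500, t_end = 3150, is_supplementary = TRUE))
  }))
  ids <- unique(frags$read_id)
  arms <- list(clean = ids, raw = ids, filtered = ids)
  scan <- mosaic_gradient_scan(frags, arms, af_values = seq(0.01, 0.08, 0.01))
  expect_equal(nrow(scan), 8L * 2L)
  expect_true(all(scan$error_rate == 0))           # identical arms
})
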