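test_that("PAF lines parse to normalized fragment records", {
  paf <- withr::local_tempfile(fileext = ".paf")
  writeLines(c(
    "r1\t1500\t0\t700\t+\tchr1\t10000\t100\t800\t650\t700\t60",
    "r1\t1500\t750\t1400\t-\tchr1\t10000\t1800\t2450\t600\t650\t60\ttp:A:P",
    "r2\t900\t0\t900\t+\tchr2\t10000\t0\t900\t880\t900\t55\ttp:A:S"
  ), paf)
  frags <- read_alignments(paf)
  # the tp:A:S secondary is dropped on ingest
  expect_equal(nrow(frags), 2L)
  expect_equal(frags$read_id[1], "r1")
  expect_equal(frags$read_len[1], 1500L)
  expect_equal(frags$q_start[1], 0L)
  expect_equal(frags$q_end[1], 700L)
  expect_equal(frags$strand, c("+", "-"))
  expect_equal(frags$target[1], "chr1")
  expect_equal(frags$t_start[1], 100L)
  expect_equal(frags$t_end[1], 800L)
  expect_equal(frags$mapq[1], 60L)
  # untagged continuation records of a read are supplementary
  expect_equal(frags$is_supplementary, c(FALSE, TRUE))
})

test_that("empty and malformed PAF input behave as configured", {
  paf <- withr::local_tempfile(fileext = ".paf")
  writeLines(character(), paf)
  expect_equal(nrow(read_alignments(paf)), 0L)

  writeLines(c("r1\t1500\t0\t700\t+\tchr1\t10000\t100\t800\t650\t700\t60",
               "broken\tline"), paf)
  expect_warning(frags <- read_alignments(paf, on_error = "skip"), "malformed")
  expect_equal(nrow(frags), 1L)
  expect_error(read_alignments(paf, on_error = "abort"), "malformed")
})

test_that("SAM records convert coordinates and flags correctly", {
  sam <- withr::local_tempfile(fileext = ".sam")
  seq1 <- strrep("A", 1500)
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:chr1\tLN:10000",
    sprintf("r1\t0\tchr1\t101\t60\t700M800S\t*\t0\t0\t%s\t*", seq1),
    "r1\t2048\tchr1\t2001\t60\t700H650M150H\t*\t0\t0\t*\t*",
    "r2\t16\tchr1\t501\t60\t300S500M700S\t*\t0\t0\t*\t*",
    "r3\t256\tchr1\t901\t0\t100M\t*\t0\t0\t*\t*"
  ), sam)
  frags <- read_alignments(sam, format = "sam")
  frags <- frags[order(frags$read_id, frags$q_start), ]
  expect_equal(nrow(frags), 3L)  # secondary (flag 256) dropped
  # primary: SAM pos 101 -> 0-based 100
  r1p <- frags[frags$read_id == "r1" & !frags$is_supplementary, ]
  expect_equal(r1p$q_start, 0L)
  expect_equal(r1p$q_end, 700L)
  expect_equal(r1p$t_start, 100L)
  expect_equal(r1p$t_end, 800L)
  # flag 2048 supplementary with hard clips reconstructs read length
  r1s <- frags[frags$read_id == "r1" & frags$is_supplementary, ]
  expect_true(r1s$is_supplementary)
  expect_equal(r1s$read_len, 1500L)
  expect_equal(r1s$q_start, 700L)
  expect_equal(r1s$q_end, 1350L)
  # minus strand: clip roles swap into original read orientation
  r2 <- frags[frags$read_id == "r2", ]
  expect_equal(r2$strand, "-")
  expect_equal(r2$q_start, 700L)
  expect_equal(r2$q_end, 1200L)
})

test_that("filter_mapq retains exactly the records at or above the cutoff", {
  frags <- rbind(frag_row(mapq = 60), frag_row(read_id = "r2", mapq = 59),
                 frag_row(read_id = "r3", mapq = 60))
  expect_equal(nrow(filter_mapq(frags, 60)), 2L)
  expect_equal(filter_mapq(frags, 0), frags)        # identity at 0
  frags0 <- frag_row(mapq = 0)
  expect_equal(nrow(filter_mapq(frags0, 60)), 0L)
  # idempotence
  once <- filter_mapq(frags, 60)
  expect_identical(filter_mapq(once, 60), once)
  # per-read mode discards the whole read when any fragment fails
  two <- rbind(frag_row(mapq = 60), frag_row(q_start = 800, q_end = 1400,
                                             mapq = 10, is_supplementary = TRUE))
  expect_equal(nrow(filter_mapq(two, 60, per_read = TRUE)), 0L)
})

test_that("group_by_read partitions input and flags candidates", {
  frags <- rbind(
    frag_row(), chimera_frags("inverted_repeat")[2, ],
    frag_row(q_start = 100, q_end = 650, is_supplementary = TRUE),
    frag_row(read_id = "r2", read_len = 900, q_end = 900))
  g <- group_by_read(frags)
  expect_equal(nrow(g$fragments), nrow(frags))     # conservation
  expect_equal(sort(g$reads$n_fragments), c(1L, 3L))
  expect_true(g$reads$candidate[g$reads$read_id == "r1"])
  expect_false(g$reads$candidate[g$reads$read_id == "r2"])
  # single primary-only read is never a candidate
  solo <- group_by_read(frag_row())
  expect_false(solo$reads$candidate)
  # two fragments, one supplementary -> candidate
  two <- group_by_read(chimera_frags("cross"))
  expect_true(two$reads$candidate)
  # conflicting read_len aborts
  bad <- rbind(frag_row(), frag_row(read_len = 2000))
  expect_error(group_by_read(bad), "conflicting read_len")
})

test_that("fragment tables round-trip through PAF", {
  frags <- rbind(chimera_frags("inverted_repeat"),
                 chimera_frags("cross")[2, ],
                 frag_row(read_id = "z9", read_len = 4000, q_end = 4000,
                          t_start = 0, t_end = 4000))
  frags$read_id[3] <- "r1b"
  paf <- withr::local_tempfile(fileext = ".paf")
  write_paf(frags, paf)
  back <- read_alignments(paf)
  ord <- order(back$read_id, back$q_start)
  back <- back[ord, ]
  orig <- frags[order(frags$read_id, frags$q_start), ]
  rownames(back) <- rownames(orig) <- NULL
  expect_equal(back, orig)
})

test_that("fragment TSV interchange round-trips", {
  frags <- chimera_frags("gapped")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_fragments_tsv(frags, tsv)
  back <- read_fragments_tsv(tsv)
  rownames(back) <- rownames(frags) <- NULL
  expect_equal(back, frags)
})
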