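test_that("overlap ratio matches interval arithmetic", {
  a <- frag_row(q_start = 0, q_end = 700)
  b <- frag_row(q_start = 750, q_end = 1500)
  expect_equal(compute_overlap_ratio(a, b), 0)
  # overlap 10 over min span 600
  b2 <- frag_row(q_start = 690, q_end = 1290)
  expect_equal(compute_overlap_ratio(a, b2), 10 / 600)
  expect_equal(compute_overlap_ratio(a, a), 1)
})

test_that("overlap ratio is symmetric and matches a brute-force oracle", {
  set.seed(11)
  for (i in 1:200) {
    s1 <- sample(0:1400, 1); e1 <- s1 + sample(1:600, 1)
    s2 <- sample(0:1400, 1); e2 <- s2 + sample(1:600, 1)
    a <- frag_row(q_start = s1, q_end = e1, read_len = 2100)
    b <- frag_row(q_start = s2, q_end = e2, read_len = 2100)
    # oracle: count shared integer positions directly
    ov <- length(intersect(seq(s1, e1 - 1), seq(s2, e2 - 1)))
    expected <- ov / min(e1 - s1, e2 - s2)
    expect_equal(compute_overlap_ratio(a, b), expected)
    expect_equal(compute_overlap_ratio(b, a), compute_overlap_ratio(a, b))
  }
})

test_that("classify_read applies the geometric rule set", {
  fetch <- random_ref_fetch()
  # inverted repeat: same chromosome, opposite strands
  call <- classify_read(chimera_frags("inverted_repeat"))
  expect_equal(call$chimera_type, "inverted_repeat")
  expect_equal(call$breakpoint, 725L)            # midpoint of the q gap
  expect_equal(call$combined_fraction, (700 + 650) / 1500)
  # single-fragment read is normal
  expect_equal(classify_read(frag_row())$chimera_type, "normal")
  # cross: different chromosomes, homology below 5%
  expect_equal(classify_read(chimera_frags("cross"), ref_fetch = fetch)$chimera_type,
               "cross")
  # gapped: same chromosome, same strand, reference gap 6100 > 5000
  expect_equal(classify_read(chimera_frags("gapped"), ref_fetch = fetch)$chimera_type,
               "gapped")
  # fragment below the 500 bp gate stays normal
  short <- chimera_frags("inverted_repeat")
  short$q_start[2] <- 1000L                       # span 400
  expect_equal(classify_read(short)$chimera_type, "normal")
  # cross without a reference cannot pass the homology screen
  noref <- classify_read(chimera_frags("cross"))
  expect_equal(noref$chimera_type, "normal")
  expect_match(noref$warning, "homology")
})

test_that("small reference gaps and same-strand overlaps stay normal", {
  g <- chimera_frags("gapped")
  g$t_start[2] <- 2000L; g$t_end[2] <- 2650L      # gap 300 < 5000
  expect_equal(classify_read(g, ref_fetch = random_ref_fetch())$chimera_type,
               "normal")
  # heavy read-space overlap fails the 0.05 gate
  ov <- chimera_frags("inverted_repeat")
  ov$q_start[2] <- 200L
  expect_equal(classify_read(ov)$chimera_type, "normal")
})

test_that("homology similarity is 1 for self and reverse complement, ~0 for random pairs", {
  s <- random_dna(500, seed = 5)
  expect_equal(homology_similarity(s, s), 1)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(homology_similarity(s, rc), 1)
  expect_error(homology_similarity(s, "ACGTX"), "non-IUPAC")
  # empirical null: independent uniform sequences score below the 5% screen
  set.seed(99)
  sims <- replicate(25, {
    homology_similarity(random_dna(2000), random_dna(2000))
  })
  expect_true(all(sims < 0.05))
})

test_that("summarize_chimeras reports counts, ratios and the inverted-repeat share", {
  mk_calls <- function(types) {
    data.frame(read_id = sprintf("r%04d", seq_along(types)),
               chimera_type = types, stringsAsFactors = FALSE)
  }
  s <- summarize_chimeras(mk_calls(c(rep("inverted_repeat", 2), "cross",
                                     rep("normal", 97))))
  expect_equal(unname(s$ratios["inverted_repeat"]), 0.02)
  expect_equal(unname(s$ratios["cross"]), 0.01)
  expect_equal(s$fp_ratio, 0.03)
  # the ligation worked example: 7.33% inverted of 7.35% total -> 99.73% share
  s2 <- summarize_chimeras(mk_calls(c(rep("inverted_repeat", 733), "cross",
                                      "gapped", rep("normal", 9265))))
  expect_equal(s2$fp_ratio, 0.0735)
  expect_equal(round(100 * s2$inverted_repeat_share, 2), 99.73)
  # all normal -> zero total; empty input -> NA ratios
  expect_equal(summarize_chimeras(mk_calls(rep("normal", 5)))$fp_ratio, 0)
  empty <- summarize_chimeras(mk_calls(character()))
  expect_true(is.na(empty$fp_ratio))
  # length binning uses 1000 bp intervals
  calls <- mk_calls(c("inverted_repeat", "normal", "normal"))
  lens <- stats::setNames(c(1500, 1700, 3200), calls$read_id)
  s3 <- summarize_chimeras(calls, lens)
  expect_equal(s3$by_length$bin, c(1000, 3000))
  expect_equal(s3$by_length$chimera_ratio, c(0.5, 0))
})

test_that("every read gets exactly one type and gates act monotonically", {
  sim <- simulate_run(sim_config(n_reads = 150, seed = 21), signals = FALSE)
  fetch <- reference_accessor(sim$reference)
  calls <- classify_reads(sim$frags, ref_fetch = fetch)
  expect_equal(sort(calls$read_id), sort(unique(sim$frags$read_id)))
  expect_true(all(calls$chimera_type %in%
                    c("inverted_repeat", "cross", "gapped", "normal")))
  n_chim <- function(cfg) {
    sum(classify_reads(sim$frags, cfg, fetch)$chimera_type != "normal")
  }
  base <- n_chim(detector_config())
  expect_lte(n_chim(detector_config(min_frag_len = 1200)), base)
  expect_lte(n_chim(detector_config(min_combined_fraction = 0.95)), base)
})
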