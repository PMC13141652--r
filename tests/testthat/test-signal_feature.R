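test_that("signal tables round-trip exactly, with and without base maps", {
  sigs <- list(
    raw_signal("a", c(1.5, 2.25, -3.125, 90)),
    raw_signal("b", 1:10 * 1.0, base_to_signal = c(0L, 3L, 5L, 9L)),
    raw_signal("c", rep(88.125, 5)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signals(sigs, path, digits = 12)
  back <- read_signals(path)
  expect_equal(length(back), 3L)
  expect_equal(back$a$samples, sigs[[1]]$samples)
  expect_equal(back$b$base_to_signal, c(0L, 3L, 5L, 9L))
  expect_null(back$a$base_to_signal)
  # empty container -> empty stream
  writeLines(character(), path)
  expect_equal(length(read_signals(path)), 0L)
  # FAST5 input is refused with guidance
  expect_error(read_signals(path, format = "fast5"), "signal-table")
})

test_that("raw_signal enforces its invariants", {
  expect_error(raw_signal("x", numeric()), "empty")
  expect_error(raw_signal("x", 1:10, base_to_signal = c(5L, 2L)),
               "non-decreasing")
  expect_error(raw_signal("x", 1:10, base_to_signal = c(0L, 12L)),
               "outside")
})

test_that("breakpoint mapping uses the base map or proportional fallback", {
  sig <- raw_signal("x", rep(0, 40000))
  expect_equal(breakpoint_to_signal_index(sig, 500, 1000), 20000L)
  expect_equal(breakpoint_to_signal_index(sig, 0, 1000), 0L)
  expect_equal(breakpoint_to_signal_index(sig, 1000, 1000), 39999L)
  sigm <- raw_signal("y", rep(0, 100), base_to_signal = as.integer(seq(0, 90, by = 10)))
  expect_equal(breakpoint_to_signal_index(sigm, 3, 10), 30L)
  expect_error(breakpoint_to_signal_index(sig, 2000, 1000))
})

test_that("smoothed segments are detected at constructed positive controls", {
  x <- noisy_trace(30000, level = 90, sd = 10, seed = 2)
  bp <- 15000L
  x[(bp + 1):(bp + 500)] <- 54             # flat low-level insert
  sig <- raw_signal("pos", x)
  rep <- detect_smoothed_segment(sig, bp)
  expect_true(rep$has_smoothed_segment)
  expect_gte(rep$segment_start, bp - 50)
  expect_lte(rep$segment_end, bp + 550)
  expect_lt(rep$segment_sd_ratio, 0.3)
  expect_lt(rep$segment_mean_ratio, 1)
})

test_that("stationary noise and degenerate flat traces do not fire", {
  fired <- vapply(1:100, function(i) {
    sig <- raw_signal("null", noisy_trace(12000, seed = 1000 + i))
    detect_smoothed_segment(sig, 6000L)$has_smoothed_segment
  }, logical(1))
  expect_lte(mean(fired), 0.01)            # null rate calibrated at >= 99% quiet
  flat <- raw_signal("flat", rep(5, 10000))
  expect_false(detect_smoothed_segment(flat, 5000L)$has_smoothed_segment)
})

test_that("detection is translation-equivariant and scale-invariant", {
  cfg <- feature_config(head_trim = 0)
  x <- noisy_trace(20000, seed = 31)
  bp <- 9000L
  x[(bp + 1):(bp + 400)] <- 50
  base <- detect_smoothed_segment(raw_signal("t", x), bp, cfg)
  k <- 750L
  shifted <- c(x[(20000 - k + 1):20000], x[1:(20000 - k)])  # circular shift by +k
  rep_k <- detect_smoothed_segment(raw_signal("t", shifted), bp + k, cfg)
  expect_true(base$has_smoothed_segment && rep_k$has_smoothed_segment)
  expect_equal(rep_k$segment_start - base$segment_start, k)
  expect_equal(rep_k$segment_end - base$segment_end, k)
  # multiplying the trace by c > 0 leaves the ratio gates unchanged
  scaled <- detect_smoothed_segment(raw_signal("t", 3.7 * x), bp, cfg)
  expect_equal(scaled$has_smoothed_segment, base$has_smoothed_segment)
  expect_equal(scaled$segment_start, base$segment_start)
})

test_that("prevalence table recovers fractions and degenerate tests", {
  reports <- data.frame(
    read_id = sprintf("r%03d", 1:200),
    chimera_type = rep(c("inverted_repeat", "normal"), each = 100),
    has_smoothed_segment = c(rep(TRUE, 100), rep(FALSE, 100)),
    stringsAsFactors = FALSE)
  prev <- smoothed_segment_prevalence(reports)
  expect_equal(unname(prev$fractions["inverted_repeat"]), 1)
  expect_equal(unname(prev$fractions["normal"]), 0)
  expect_true(is.na(prev$fractions["cross"]))
  expect_lt(prev$tests$p_value[1], 1e-6)
  # identical groups give maximal p
  same <- reports
  same$has_smoothed_segment <- rep(c(TRUE, FALSE), 100)
  prev2 <- smoothed_segment_prevalence(same)
  expect_equal(prev2$tests$p_value[1], 1)
})

test_that("per-type prevalence recovers the simulator's insertion probabilities", {
  sim <- simulate_run(sim_config(
    n_reads = 400, chimera_rates = c(inverted_repeat = 0.5, cross = 0, gapped = 0),
    seed = 8))
  calls <- classify_reads(filter_mapq(sim$frags))
  anchors <- stats::setNames(
    ifelse(is.na(sim$truth$junction_sample), sim$truth$anchor_sample,
           sim$truth$junction_sample), sim$truth$read_id)
  fr <- feature_reports(sim$signals, calls, sim$read_lens, anchors = anchors)
  prev <- smoothed_segment_prevalence(fr)
  n_chim <- sum(fr$chimera_type != "normal")
  n_norm <- sum(fr$chimera_type == "normal")
  tol_c <- 3 * sqrt(0.47 * 0.53 / n_chim)
  tol_n <- 3 * sqrt(0.13 * 0.87 / n_norm)
  expect_lt(abs(prev$fractions[["inverted_repeat"]] - 0.47), tol_c)
  expect_lt(abs(prev$fractions[["normal"]] - 0.13), tol_n)
  # the detector agrees with the simulator's per-read truth almost everywhere
  agree <- mean(fr$has_smoothed_segment ==
                  sim$truth$has_smoothed_segment[match(fr$read_id, sim$truth$read_id)])
  expect_gte(agree, 0.97)
})
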