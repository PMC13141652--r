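# Shared fixture builders: everything is generated in code at test time.

frag_row <- function(read_id = "r1", read_len = 1500L, q_start = 0L,
                     q_end = 700L, strand = "+", target = "chr1",
                     t_start = 100L, t_end = 800L, mapq = 60L,
                     is_supplementary = FALSE) {
  data.frame(read_id = read_id, read_len = as.integer(read_len),
             q_start = as.integer(q_start), q_end = as.integer(q_end),
             strand = strand, target = target, t_start = as.integer(t_start),
             t_end = as.integer(t_end), mapq = as.integer(mapq),
             is_supplementary = is_supplementary, stringsAsFactors = FALSE)
}

# A two-fragment read laid out for a given chimera geometry.
chimera_frags <- function(type = c("inverted_repeat", "cross", "gapped"),
                          read_len = 1500L) {
  type <- match.arg(type)
  a <- frag_row(q_start = 0L, q_end = 700L, strand = "+", target = "chr1",
                t_start = 1000L, t_end = 1700L)
  b <- switch(type,
    inverted_repeat = frag_row(q_start = 750L, q_end = 1400L, strand = "-",
                               target = "chr1", t_start = 1800L, t_end = 2450L,
                               is_supplementary = TRUE),
    cross = frag_row(q_start = 750L, q_end = 1400L, strand = "+",
                     target = "chr2", t_start = 5000L, t_end = 5650L,
                     is_supplementary = TRUE),
    gapped = frag_row(q_start = 750L, q_end = 1400L, strand = "+",
                      target = "chr1", t_start = 7800L, t_end = 8450L,
                      is_supplementary = TRUE))
  rbind(a, b)
}

# Reference accessor over random sequences: unrelated targets, so the
# homology screen sees ~zero similarity.
random_ref_fetch <- function(seed = 42L, len = 20000L) {
  set.seed(seed)
  seqs <- list(
    chr1 = paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
    chr2 = paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""))
  function(target, start, end) substr(seqs[[target]], start + 1L, end)
}

# Pore-like synthetic trace: positive levels, Gaussian noise.
noisy_trace <- function(n = 20000L, level = 90, sd = 10, seed = 1L) {
  set.seed(seed)
  stats::rnorm(n, level, sd)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}
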