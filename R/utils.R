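# Evaluate code under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library calls never perturb user-level randomness.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# Stable small integer key from a read id, used to derive per-read seeds
# that are independent of processing order.
id_key <- function(id) {
  v <- utf8ToInt(id)
  as.integer(sum(v * seq_along(v)) %% 1000003L)
}

#' @useDynLib nanochimera, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom data.table data.table as.data.table fread
#' @importFrom stats setNames
NULL

.datatable.aware <- TRUE
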