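# Internal helpers shared across stages.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom withr with_seed with_preserve_seed
NULL

# Polynomial string hash onto [0, 2^31 - 2]; stable across platforms.
hash_id <- function(ids) {
  vapply(ids, function(s) {
    h <- 0
    for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Deterministic per-cell uniform draw keyed on (seed, cell id), independent of
# row order. This is what makes every seeded sampling stage permutation
# invariant: a cell's draw travels with its id, not its row index.
cell_priority <- function(ids, seed) {
  h <- hash_id(ids)
  withr::with_preserve_seed(
    vapply(h, function(hi) {
      set.seed((hi + seed) %% 2147483647)
      stats::runif(1)
    }, numeric(1))
  )
}

# Derive an independent substream seed for a named stage/sample.
derive_seed <- function(seed, label) {
  (hash_id(as.character(label)) + as.numeric(seed) * 10007) %% 2147483647
}

timestamp_now <- function() format(Sys.time(), "%Y-%m-%d %H:%M:%OS3", tz = "UTC")

log_entry <- function(step, params = list()) {
  list(step = step, params = params, time = timestamp_now())
}

stop_ct <- function(...) stop(..., call. = FALSE)
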