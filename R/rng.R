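# Seed management: one root seed per run, independent derived seeds for
# network generation vs dynamics so adding a generator draw never shifts
# the dynamics noise stream.

#' Derive a child seed from a root seed
#'
#' Deterministically maps a root seed plus any number of integer tags
#' (e.g. run index, grid-cell index) to a new seed in `[1, 2^31 - 2]`.
#' Used so that every run, network draw and estimator repetition in a
#' sweep has its own reproducible stream.
#'
#' @param seed Integer root seed.
#' @param ... Integer tags identifying the consumer.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  x <- as.double(seed) %% m
  for (tag in c(...)) {
    x <- (x * 48271 + as.double(tag) %% m + 1) %% m
  }
  as.integer(x %% (m - 1) + 1)
}

# Evaluate expr under a temporary RNG state seeded with `seed`;
# restores the caller's stream afterwards. seed = NULL uses the current
# stream (and advances it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialize a stream to save
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
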