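# Internal helpers shared across the package.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library calls never perturb a user's random stream.
with_seed <- function(seed, code) {
  seed <- as_count(seed, "seed")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic substream seed for operation `i` under a single global seed.
# Stays below 2^31 - 1 so it is always a valid R integer seed.
substream <- function(seed, i) {
  as.integer((as.double(seed) + 7919 * as.double(i)) %% 2147483647)
}

as_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != trunc(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  x
}

as_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single number in [0, 1]", name), call. = FALSE)
  x
}

# Two-significant-figure reporting used throughout the printed tables; full
# precision is always retained in the objects themselves.
signif2 <- function(x) signif(x, 2)

fmt_rate <- function(x, bound = FALSE) {
  s <- format(signif2(x), trim = TRUE, scientific = TRUE)
  if (bound) paste0("<", s) else s
}
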