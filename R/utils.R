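# Internal helpers: seed handling and small numerics.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations in the package
# funnel through this so results are reproducible and side-effect free.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation. Keeps derived seeds inside the 32-bit
# integer range whatever the base seed, and separates parallel streams (e.g.
# one per participant or per permutation batch) without seed reuse.
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed, scientific = FALSE), ...), collapse = "/")
  bytes <- utf8ToInt(key)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  as.integer(h + 1)
}

# sample() without the length-1 surprise.
sample_vec <- function(x, size = length(x), replace = FALSE) {
  x[sample.int(length(x), size = size, replace = replace)]
}

# Nearest-rank percentile (ceiling rule), used for permutation thresholds so
# they are reproducible across platforms.
nearest_rank <- function(x, prob) {
  s <- sort(x)
  s[max(1L, ceiling(prob * length(s)))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
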