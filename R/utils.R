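# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library functions never clobber user randomness.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Deterministically derive a child seed from a root seed and integer tags,
# so independent work units (subjects, condition pairs, stages) draw from
# reproducible substreams regardless of execution order. Stays below 2^31.
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  x <- as.numeric(seed) %% m
  for (tag in c(...)) {
    x <- (x * 48271 + as.numeric(tag) + 1) %% m
  }
  as.integer(x)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

# Strict upper-triangle vectorization used for all RDM comparisons.
upper_vec <- function(m) m[upper.tri(m)]
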