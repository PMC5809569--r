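# internal helpers shared across modules

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
# All randomized entry points funnel through this so that a user-level seed
# fully determines output without clobbering the session RNG.
with_seed <- function(seed, code) {
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
  force(code)
}

# Derive a child seed from (seed, stream index), kept inside 32-bit range so
# independent streams (per design version, per EM start, per bootstrap rep)
# are reproducible in isolation.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + as.double(stream) * 16807) %% 2147483399 + 1
}

# Gumbel(location 0, scale s) draws; s = 0 means exactly no noise.
rgumbel <- function(n, scale = 1) {
  if (scale == 0) return(numeric(n))
  -scale * log(-log(stats::runif(n)))
}

# Softmax along groups: x is a vector, group an integer id per element.
# Returns probabilities summing to 1 within each group. Numerically stable.
grouped_softmax <- function(x, group, n_groups = max(group)) {
  m <- vapply(split(x, group), max, numeric(1))
  ex <- exp(x - m[group])
  denom <- rowsum(ex, group, reorder = TRUE)
  ex / denom[group, 1L]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
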