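# Internal helpers shared across modules.

# Derive a reproducible sub-seed from a master seed and a stream name, so that
# every stochastic component draws from its own named substream. Kept below
# 2^31 so it is always a valid R integer seed.
deriveSeed <- function(seed, stream) {
  codes <- utf8ToInt(stream)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483563
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483563)
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

cosineSimilarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# status vocabulary used throughout
.STATUS_LEVELS <- c("MUT", "WT", "CND")
.CALL_LEVELS <- c("RR", "RA", "AA", "NC")
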