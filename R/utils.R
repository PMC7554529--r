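# Internal helpers: deterministic sub-seeding and a scoped RNG.

# Derive a reproducible 32-bit sub-seed from a root seed and a stream name.
# Named streams keep synthesis, weight init, shuffling and candidate sampling
# independent of each other while everything hangs off one root seed.
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(as.character(name))
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stopf <- function(class, fmt, ...) {
  rlang::abort(sprintf(fmt, ...), class = c(class, "midecoder_error"))
}

`%??%` <- function(x, y) if (is.null(x)) y else x
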