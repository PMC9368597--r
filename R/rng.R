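# Independent RNG streams.
#
# The corpus generator draws demography, restriction structure, text noise
# and visit intervals from separate streams so that changing, say, a text
# noise rate does not shift the demographic draws. Each stream owns a saved
# copy of .Random.seed; evaluation under a stream swaps it in and out of
# the global environment (the only place R's RNG state lives).

rng_stream <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  env <- new.env(parent = emptyenv())
  env$state <- state
  class(env) <- "ohppfwa_rng_stream"
  env
}

with_stream <- function(stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

# Derive a bounded child seed from a master seed and a channel label,
# stable across platforms (kept below 2^31 - 1).
derive_seed <- function(seed, channel) {
  h <- sum(utf8ToInt(channel) * seq_along(utf8ToInt(channel)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}
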