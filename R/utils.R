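# Internal helpers.

# Evaluate `expr` under a given RNG seed without disturbing the caller's RNG
# stream. All stochastic components in the package (bootstraps, simulation
# nulls, the data generator) route their draws through this.
local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream index, kept within the
# 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 1103L + as.double(stream) * 7919L) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
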