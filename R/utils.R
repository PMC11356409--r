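# small shared helpers

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  eval.parent(substitute(expr))
}

# Deterministically combine seed components into a valid 32-bit seed.
mix_seed <- function(...) {
  parts <- as.numeric(c(...))
  s <- 0
  for (p in parts) s <- (s * 69069 + p + 1) %% 2147483647
  as.integer(s)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)
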