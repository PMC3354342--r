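# Evaluate `expr` under a locally set RNG seed, restoring the caller's RNG
# state afterwards.  seed = NULL leaves the global stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-stage / per-replicate child seeds below 2^31.
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max, n))
}

# Laplace(0, scale) draws as the difference of two exponentials.
rlaplace <- function(n, scale = 1) {
  rexp(n, rate = 1 / scale) - rexp(n, rate = 1 / scale)
}
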