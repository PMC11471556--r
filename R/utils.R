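# Run expr with a local RNG state seeded by `seed`; the caller's RNG stream
# is untouched. All stochastic operations in the package funnel through this
# so results are reproducible per (input, seed) pair.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Deterministic 31-bit seed derived from a master seed and a stage label.
derive_seed <- function(master_seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(master_seed) * 131 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
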