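# Small internal utilities.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All stochastic entry points funnel
# through this so runs are reproducible without clobbering user RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# cor() that maps undefined correlations (zero-variance input) to r = 0
# so batch runs never crash on flat vectors.
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}
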