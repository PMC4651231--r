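# Seed discipline: every stochastic operation takes an explicit seed and
# leaves the caller's RNG state untouched.

#' Evaluate an expression under a local RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards, so stochastic package
#' operations never leak RNG state.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, i) {
  (as.integer(seed) %% 1000003L) * 2017L + as.integer(i) %% 1000003L
}
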