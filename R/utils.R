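# Seed hygiene: every stochastic operation takes an explicit seed and
# leaves the global RNG state untouched; sub-streams are derived
# deterministically so one top-level seed drives the whole pipeline.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with `set.seed(seed)` and restores the caller's
#' `.Random.seed` afterwards, so seeded operations never perturb global
#' random state.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
local_seed <- function(seed, expr) {
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

#' Derive a sub-stream seed
#'
#' Deterministic splitting of one top-level seed into independent
#' sub-stream seeds (kept below 2^31).
#'
#' @param seed Integer top-level seed.
#' @param k Sub-stream index.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483647)
}
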