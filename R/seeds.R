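# Seed plumbing shared by the simulation and training code.
#
# Every stochastic routine in the package takes an explicit integer seed and
# restores the caller's RNG state on exit, so a fixed top-level seed pins the
# whole pipeline while unrelated user code is unaffected.

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the R random number generator seeded to `seed`, then
#' restores the previous RNG state (including "no state yet").
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  } else {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive reproducible sub-seeds from a base seed
#'
#' Draws `n` distinct integer seeds from the stream pinned by `base_seed`.
#' Used to give each run / optimizer / purpose its own independent,
#' individually reproducible substream.
#'
#' @param base_seed Integer base seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seeds <- function(base_seed, n) {
  with_seed(base_seed, sample.int(.Machine$integer.max - 1L, n))
}
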