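#' @importFrom stats rnorm runif setNames aggregate
#' @importFrom utils head read.delim write.table
NULL

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All stochastic generators in the package
# route their draws through this so a call is fully determined by its
# explicit seed argument and never perturbs the session RNG.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible child seed
#'
#' Maps a parent seed and an index to a new seed within the 32-bit integer
#' range `set.seed()` requires. Used to give every stochastic sub-step of a
#' pipeline its own deterministic stream.
#'
#' @param seed parent integer seed.
#' @param i stream index.
#' @return A numeric seed below 2^31.
#' @export
child_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + as.numeric(i) * 16807) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
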