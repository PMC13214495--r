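## Small shared numeric helpers.

db_to_lin <- function(db) 10^(db / 20)

lin_to_db <- function(a) 20 * log10(a)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @useDynLib hearsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
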