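#' Evaluate an expression under a temporary seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards, so seeded internals do not disturb the caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
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

#' Derive a child seed deterministically
#'
#' Splittable seeding: mixes a run seed with any number of integer indices
#' (generation, individual, repeat, ...) into a new seed below 2^31, so every
#' simulated experiment gets its own reproducible stream.
#'
#' @param seed base integer seed.
#' @param ... integer indices to mix in.
#' @return a derived integer seed.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(seed, ...)
  s <- 0
  m <- 2147483563            # < 2^31, product with multiplier stays exact in doubles
  for (v in idx) s <- (s * 69069 + (as.numeric(v) %% m) + 1) %% m
  as.integer(s)
}
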