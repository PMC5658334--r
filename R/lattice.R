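#' Enumerate the formulation lattice
#'
#' Evenly spaced combinatorial search over the 4-oil simplex: the four
#' single-oil recipes, plus every composition of 1 in steps of `granularity`
#' over each pair, triple and quadruple of oils with all members of the
#' subset strictly positive (the single-oil extremes belong to the `single`
#' class only). At 10% granularity this yields 282 multi-oil formulations:
#' 54 pair (6 subsets x 9), 144 triple (4 x 36) and 84 quadruple.
#'
#' Genomes are built from integer step counts divided once, so the simplex
#' constraint holds exactly; rows are in lexicographic order over the
#' canonical oil order.
#'
#' @param granularity step size; `1/granularity` must be an integer.
#' @return a `lattice_plan` data frame: `subset` (oils joined by `+`),
#'   `class` (`single`/`pair`/`triple`/`quad`) and the four fraction columns.
#' @export
enumerate_lattice <- function(granularity = 0.1) {
  m <- 1 / granularity
  if (abs(m - round(m)) > 1e-9 || m < 1)
    stop("1/granularity must be a positive integer")
  m <- as.integer(round(m))
  oils <- oil_names()
  class_names <- c("single", "pair", "triple", "quad")
  rows <- list()
  for (k in 1:4) {
    subsets <- utils::combn(4, k, simplify = FALSE)
    for (sub in subsets) {
      comps <- if (k == 1L) matrix(m, 1, 1) else compositions(m, k)
      for (r in seq_len(nrow(comps))) {
        g <- numeric(4); g[sub] <- comps[r, ] / m
        rows[[length(rows) + 1L]] <-
          c(list(subset = paste(oils[sub], collapse = "+"),
                 class = class_names[k]),
            as.list(stats::setNames(g, oils)))
      }
    }
  }
  plan <- do.call(rbind, lapply(rows, as.data.frame))
  structure(plan, class = c("lattice_plan", "data.frame"))
}

# all ordered k-tuples of positive integers summing to total, lexicographic
compositions <- function(total, k) {
  if (total < k) return(matrix(numeric(0), 0, k))
  if (k == 1L) return(matrix(total, 1, 1))
  out <- list()
  for (first in seq_len(total - k + 1L)) {
    rest <- compositions(total - first, k - 1L)
    out[[first]] <- cbind(first, rest)
  }
  do.call(rbind, out)
}

#' Run the lattice search
#'
#' Evaluates every planned formulation `repeats` times in each arena. By
#' default only the multi-oil formulations are run (the published totals --
#' 282 formulations, 1410 videos for one arena -- exclude the four
#' single-oil recipes, which the platform tested once each).
#'
#' @param plan a [enumerate_lattice()] plan.
#' @param arenas list of arenas.
#' @param repeats experiments per formulation per arena.
#' @param evaluator function `(genome, arena, seed) -> fitness`.
#' @param seed base seed for the derived per-experiment seeds.
#' @param include_singles include the `single`-class recipes.
#' @return data frame: `subset`, `class`, four fraction columns, `arena`,
#'   `repeat_idx`, `seed`, `fitness` -- one row per experiment.
#' @export
run_lattice <- function(plan, arenas, repeats = 5, evaluator, seed = 1L,
                        include_singles = FALSE) {
  stopifnot(is.data.frame(plan), is.function(evaluator))
  if (inherits(arenas, "arena")) arenas <- list(arenas)
  if (!include_singles) plan <- plan[plan$class != "single", , drop = FALSE]
  if (!nrow(plan))
    return(data.frame(subset = character(0), class = character(0),
                      octanol = numeric(0), dep = numeric(0),
                      octanoic = numeric(0), pentanol = numeric(0),
                      arena = character(0), repeat_idx = integer(0),
                      seed = integer(0), fitness = numeric(0)))
  rows <- vector("list", nrow(plan) * length(arenas))
  n <- 0L
  for (a in seq_along(arenas)) {
    ar <- arenas[[a]]
    for (f in seq_len(nrow(plan))) {
      g <- as_genome(plan[f, oil_names()])
      seeds <- vapply(seq_len(repeats),
                      function(r) derive_seed(seed, a, f, r), integer(1))
      fit <- vapply(seeds, function(s) as.numeric(evaluator(g, ar, s)),
                    numeric(1))
      n <- n + 1L
      rows[[n]] <- data.frame(subset = plan$subset[f], class = plan$class[f],
                              octanol = g[["octanol"]], dep = g[["dep"]],
                              octanoic = g[["octanoic"]],
                              pentanol = g[["pentanol"]],
                              arena = ar$label, repeat_idx = seq_len(repeats),
                              seed = seeds, fitness = fit)
    }
  }
  do.call(rbind, rows[seq_len(n)])
}
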