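#' Fitness-weighted average genome
#'
#' The weighted genome (WG) of a population: each component's
#' fitness-weighted mean over the individuals, with a fitness-weighted
#' standard deviation about that mean (normalised weights). Used to compare
#' populations evolved in different environments.
#'
#' @param individuals list of [individual()]s; at least one must have
#'   positive fitness.
#' @return a `weighted_genome`: list with named `mean` and `sd` 4-vectors.
#' @export
weighted_genome <- function(individuals) {
  w <- vapply(individuals, function(i) i$mean_fitness, numeric(1))
  if (all(w <= 0)) stop("all fitness values are zero: weights undefined")
  w <- w / sum(w)
  G <- do.call(rbind, lapply(individuals, function(i) unclass(i$genome)))
  m <- colSums(w * G)
  s <- sqrt(colSums(w * sweep(G, 2, m)^2))
  structure(list(mean = m, sd = s), class = "weighted_genome")
}

#' @export
print.weighted_genome <- function(x, ...) {
  cat("<weighted_genome> (",
      paste(sprintf("%.0f ± %.0f", 100 * x$mean, 100 * x$sd), collapse = ", "),
      ") %\n", sep = "")
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical one-way fixed-effects ANOVA across groups (equal variances
#' assumed), returning the F statistic and its p value. Degenerate data with
#' zero variance everywhere and equal group means yields `F = 0`, `p = 1`.
#'
#' @param groups list of numeric vectors, one per group (each of length >= 2).
#' @return list with `statistic` (F), `p.value`, and the degrees of freedom
#'   `df`.
#' @export
anova_one_way <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(lengths(groups) < 2L)) stop("each group needs >= 2 observations")
  values <- unlist(groups)
  fac <- factor(rep(seq_along(groups), lengths(groups)))
  df1 <- length(groups) - 1L
  df2 <- length(values) - length(groups)
  gm <- tapply(values, fac, mean)
  ssw <- sum((values - gm[fac])^2)
  if (ssw == 0 && stats::var(gm) == 0)
    return(list(statistic = 0, p.value = 1, df = c(df1, df2)))
  ht <- stats::oneway.test(values ~ fac, var.equal = TRUE)
  list(statistic = unname(ht$statistic), p.value = unname(ht$p.value),
       df = c(df1, df2))
}

#' Encode an average genome as a 4-letter heat-map string
#'
#' Discretises each component into ten slots by rounding to one decimal
#' (round-half-up, slot `min(round(10 v), 9)`) and maps slots 0..9 to the
#' letters A..J. Components are ordered as the heat-map rows: pentanol,
#' octanoic acid, DEP, octanol. The letter convention is this package's own
#' documented choice.
#'
#' @param avg a [genome()] (typically a population-average genome).
#' @return a 4-character string.
#' @export
heatmap_encode <- function(avg) {
  g <- as_genome(avg)
  comp <- unclass(g)[c("pentanol", "octanoic", "dep", "octanol")]
  slot <- pmin(floor(10 * comp + 0.5), 9)      # round half up, capped
  paste(LETTERS[slot + 1], collapse = "")
}

#' Cross-environment fitness matrix
#'
#' Re-evaluates the final population evolved in each environment inside
#' every environment: entry `(i, j)` is the mean fitness (over individuals
#' and repeats) of the population evolved in arena `i` when tested in arena
#' `j`. The diagonal re-measures each population at home.
#'
#' @param final_gens named list (one entry per source arena) of lists of
#'   [individual()]s -- the final generations.
#' @param arenas list of arenas in matching order.
#' @param evaluator function `(genome, arena, seed) -> fitness`.
#' @param repeats experiments per individual per test arena.
#' @param seed base seed for the derived experiment seeds.
#' @return numeric matrix, rows = population origin, cols = test arena.
#' @export
cross_environment_matrix <- function(final_gens, arenas, evaluator,
                                     repeats = 5, seed = 1L) {
  stopifnot(length(final_gens) == length(arenas))
  labels <- vapply(arenas, function(a) a$label, character(1))
  M <- matrix(NA_real_, length(arenas), length(arenas),
              dimnames = list(origin = labels, tested_in = labels))
  for (i in seq_along(final_gens)) {
    for (j in seq_along(arenas)) {
      fits <- unlist(lapply(seq_along(final_gens[[i]]), function(k) {
        g <- final_gens[[i]][[k]]$genome
        vapply(seq_len(repeats), function(r)
          as.numeric(evaluator(g, arenas[[j]], derive_seed(seed, i, j, k, r))),
          numeric(1))
      }))
      M[i, j] <- mean(fits)
    }
  }
  M
}
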