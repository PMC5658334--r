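#' @useDynLib dropevo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd var predict oneway.test pt qf
#' @importFrom utils head write.csv read.csv
NULL

#' Canonical oil order of a formulation genome
#'
#' The four oils of a droplet recipe, in the fixed order used throughout the
#' package and in all serialised output: 1-octanol, diethyl phthalate (DEP),
#' octanoic acid, 1-pentanol.
#' @export
oil_names <- function() c("octanol", "dep", "octanoic", "pentanol")

#' Construct a formulation genome
#'
#' A genome is a point on the 4-component mixture simplex: the volume
#' fractions of 1-octanol, DEP, octanoic acid and 1-pentanol that define a
#' droplet recipe. Components must be non-negative and sum to 1 (within
#' 1e-9).
#'
#' @param octanol,dep,octanoic,pentanol component fractions in `[0, 1]`.
#' @return a `genome`: a named numeric vector of length 4.
#' @examples
#' genome(0.1, 0.2, 0.3, 0.4)
#' @export
genome <- function(octanol, dep, octanoic, pentanol) {
  g <- c(octanol = octanol, dep = dep, octanoic = octanoic, pentanol = pentanol)
  validate_genome(g)
}

#' @rdname genome
#' @param x numeric vector of length 4 (ordered as [oil_names()]), or a
#'   one-row data frame with the four oil columns.
#' @export
as_genome <- function(x) {
  if (is.data.frame(x)) x <- unlist(x[1, oil_names()])
  g <- as.numeric(x)
  names(g) <- oil_names()
  validate_genome(g)
}

validate_genome <- function(g) {
  if (length(g) != 4L || anyNA(g))
    stop("a genome is 4 finite oil fractions", call. = FALSE)
  if (any(g < 0)) stop("genome components must be non-negative", call. = FALSE)
  if (abs(sum(g) - 1) > 1e-9)
    stop("genome components must sum to 1 (got ", format(sum(g)), ")", call. = FALSE)
  structure(g, class = "genome")
}

is_genome <- function(x) inherits(x, "genome")

#' @export
print.genome <- function(x, ...) {
  cat("<genome> ", paste(sprintf("%s=%.3f", names(x), unclass(x)), collapse = " "), "\n")
  invisible(x)
}

#' Draw a random genome, uniform on the simplex
#'
#' Samples uniformly from the 4-component simplex (equivalently a symmetric
#' Dirichlet(1,1,1,1)) via sorted-uniform spacings. Uses R's global random
#' number generator; call [set.seed()] for reproducibility.
#'
#' @return a `genome`.
#' @export
random_genome <- function() {
  cuts <- sort(runif(3))
  as_genome(diff(c(0, cuts, 1)))
}

#' Normalise a raw recipe to the simplex
#'
#' Rescales four non-negative component amounts so they sum to 1.
#'
#' @param raw numeric vector of 4 non-negative amounts, not all zero.
#' @return a `genome` proportional to `raw`.
#' @export
normalize_genome <- function(raw) {
  raw <- as.numeric(raw)
  if (length(raw) != 4L || anyNA(raw)) stop("need 4 finite components")
  if (any(raw < 0)) stop("components must be non-negative")
  s <- sum(raw)
  if (s <= 0) stop("degenerate recipe: all components are zero")
  as_genome(raw / s)
}

#' One-point crossover of two genomes
#'
#' Takes components before a uniformly chosen interior cut point from parent
#' `a` and the rest from parent `b`, then renormalises to the simplex. Cut
#' points are drawn from \{1, 2, 3\}: a cut at the ends would clone a parent.
#'
#' @param a,b parent genomes.
#' @param cut optional fixed cut point in 1..3 (mainly for testing); default
#'   random.
#' @return the child `genome`.
#' @export
one_point_crossover <- function(a, b, cut = NULL) {
  a <- as_genome(a); b <- as_genome(b)
  k <- if (is.null(cut)) sample(1:3, 1L) else as.integer(cut)
  if (!k %in% 1:3) stop("cut point must be 1, 2 or 3")
  child <- function(k) c(unclass(a)[seq_len(k)], unclass(b)[(k + 1L):4L])
  raw <- child(k)
  if (sum(raw) <= 0) {
    # sparse complementary parents can zero the child at this cut; try the
    # other cuts, and if all are degenerate fall back to parent a
    for (k2 in sample(setdiff(1:3, k))) {
      raw <- child(k2)
      if (sum(raw) > 0) break
    }
    if (sum(raw) <= 0) return(a)
  }
  normalize_genome(raw)
}

#' Gaussian mutation of a genome
#'
#' Adds independent Normal(0, `variance`) noise to each component, clamps
#' negatives to zero and renormalises to the simplex. In the rare case that
#' clamping zeroes every component, the noise is resampled.
#'
#' @param g a genome.
#' @param variance variance of the additive noise (default 0.1, i.e. sd
#'   about 0.316).
#' @return the mutated `genome`.
#' @export
gaussian_mutation <- function(g, variance = 0.1) {
  g <- as_genome(g)
  if (variance < 0) stop("variance must be non-negative")
  if (variance == 0) return(g)
  repeat {
    raw <- pmax(unclass(g) + rnorm(4L, 0, sqrt(variance)), 0)
    if (sum(raw) > 0) return(normalize_genome(raw))
  }
}

#' Construct an evaluated individual
#'
#' An individual couples a genome with the fitness values of its repeated
#' experiments; its fitness is the arithmetic mean of the repeats.
#'
#' @param genome a `genome`.
#' @param repeat_fitnesses numeric vector of non-negative per-repeat fitness
#'   values.
#' @return an `individual` (list with `genome`, `repeat_fitnesses`,
#'   `mean_fitness`).
#' @export
individual <- function(genome, repeat_fitnesses) {
  genome <- as_genome(genome)
  repeat_fitnesses <- as.numeric(repeat_fitnesses)
  if (length(repeat_fitnesses) < 1L || anyNA(repeat_fitnesses) || any(repeat_fitnesses < 0))
    stop("repeat fitnesses must be non-negative numbers")
  structure(list(genome = genome,
                 repeat_fitnesses = repeat_fitnesses,
                 mean_fitness = mean(repeat_fitnesses)),
            class = "individual")
}

#' @export
print.individual <- function(x, ...) {
  cat(sprintf("<individual> fitness %.3f (%d repeats)\n",
              x$mean_fitness, length(x$repeat_fitnesses)))
  print(x$genome)
  invisible(x)
}

#' Roulette-wheel selection without replacement
#'
#' Selects `k` distinct individuals by sequential fitness-proportionate
#' draws: each draw picks among the remaining candidates with probability
#' proportional to `mean_fitness`, so a given individual can be selected at
#' most once. If every remaining candidate has zero fitness the draw falls
#' back to uniform sampling.
#'
#' @param population list of [individual()] objects.
#' @param k number of individuals to select (`k <= length(population)`).
#' @return list of `k` selected individuals.
#' @export
roulette_select <- function(population, k) {
  n <- length(population)
  if (n == 0L) stop("population is empty")
  if (k > n) stop("cannot select more individuals than the population holds")
  fit <- vapply(population, function(ind) ind$mean_fitness, numeric(1))
  if (any(fit < 0)) stop("fitness must be non-negative")
  remaining <- seq_len(n)
  picked <- integer(0)
  for (d in seq_len(k)) {
    w <- fit[remaining]
    if (sum(w) <= 0) w <- rep(1, length(remaining))
    idx <- if (length(remaining) == 1L) remaining else
      sample(remaining, 1L, prob = w)
    picked <- c(picked, idx)
    remaining <- setdiff(remaining, idx)
  }
  population[picked]
}

#' Serialise genomes to a data frame
#'
#' @param genomes a genome or list of genomes.
#' @return data frame with the four oil columns in canonical order.
#' @export
genomes_to_df <- function(genomes) {
  if (is_genome(genomes)) genomes <- list(genomes)
  out <- do.call(rbind, lapply(genomes, function(g) unclass(as_genome(g))))
  as.data.frame(out)
}
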