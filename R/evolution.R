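#' Genetic-algorithm configuration
#'
#' The generational GA over formulation genomes: 10 generations of 20
#' individuals, each evaluated 5 times; 10 parents chosen by roulette-wheel
#' selection survive unchanged and 10 offspring are produced by one-point
#' crossover of parent pairs followed by Gaussian mutation.
#'
#' @param generations number of generations.
#' @param pop_size individuals per generation (even).
#' @param repeats experiments per individual; fitness is their mean.
#' @param n_parents parents selected per generation; must equal `pop_size/2`.
#' @param mutation_variance variance of the Gaussian mutation.
#' @param seed run seed; every experiment seed is derived from it.
#' @param arena_schedule list of `list(arena = <arena>, generations = <int
#'   vector>)` covering every generation exactly once; `NULL` = empty arena
#'   throughout.
#' @return a `ga_config`.
#' @export
ga_config <- function(generations = 10, pop_size = 20, repeats = 5,
                      n_parents = pop_size / 2, mutation_variance = 0.1,
                      seed = 1L, arena_schedule = NULL) {
  if (n_parents != pop_size / 2)
    stop("n_parents must equal pop_size / 2")
  if (repeats < 1) stop("repeats must be >= 1")
  if (is.null(arena_schedule))
    arena_schedule <- list(list(arena = make_empty_arena(),
                                generations = seq_len(generations)))
  covered <- sort(as.integer(unlist(lapply(arena_schedule, `[[`, "generations"))))
  if (!identical(covered, seq_len(generations)))
    stop("arena_schedule must cover every generation exactly once")
  structure(list(generations = generations, pop_size = pop_size,
                 repeats = repeats, n_parents = n_parents,
                 mutation_variance = mutation_variance, seed = as.integer(seed),
                 arena_schedule = arena_schedule),
            class = "ga_config")
}

#' Environment-swap schedule
#'
#' The 30-generation schedule of the environmental-change experiment: 10
#' generations in each arena, swapped at generations 11 and 21.
#'
#' @param arenas list of arenas, in order.
#' @param gens_per_arena generations spent in each.
#' @return an arena schedule for [ga_config()].
#' @export
swap_schedule <- function(arenas = list(make_empty_arena(),
                                        make_pillar_arena(),
                                        make_lsystem_arena()),
                          gens_per_arena = 10) {
  lapply(seq_along(arenas), function(i)
    list(arena = arenas[[i]],
         generations = (i - 1) * gens_per_arena + seq_len(gens_per_arena)))
}

arena_for_generation <- function(cfg, gen) {
  for (entry in cfg$arena_schedule)
    if (gen %in% entry$generations) return(entry$arena)
  stop("generation ", gen, " not covered by the arena schedule")
}

#' Evaluate one individual
#'
#' Runs `repeats` experiments with distinct derived seeds and returns the
#' individual with its per-repeat fitness values and their mean.
#'
#' @param g a [genome()].
#' @param arena an [arena()].
#' @param repeats number of repeats.
#' @param evaluator function `(genome, arena, seed) -> fitness`.
#' @param seeds integer vector of `repeats` distinct seeds.
#' @return an [individual()].
#' @export
evaluate_individual <- function(g, arena, repeats, evaluator, seeds) {
  if (length(seeds) != repeats) stop("need one seed per repeat")
  fit <- vapply(seeds, function(s) {
    v <- tryCatch(evaluator(g, arena, s),
                  error = function(e)
                    stop("evaluator failed (seed ", s, "): ",
                         conditionMessage(e), call. = FALSE))
    as.numeric(v)
  }, numeric(1))
  individual(g, fit)
}

#' Per-generation population statistics
#'
#' Mean fitness over the population, the top and bottom quartile individuals
#' (for 20 individuals: the 5th and 15th by descending mean fitness, ties
#' kept in insertion order), and the per-component standard deviation of the
#' genomes.
#'
#' @param individuals list of [individual()]s.
#' @return list with `mean_fitness`, `top_quartile`, `bottom_quartile`,
#'   `genome_sd` (named 4-vector).
#' @export
generation_stats <- function(individuals) {
  fit <- vapply(individuals, function(i) i$mean_fitness, numeric(1))
  n <- length(fit)
  ord <- order(-fit)                       # stable: ties by insertion order
  top_i <- ord[max(1L, round(0.25 * n))]
  bot_i <- ord[min(n, round(0.75 * n))]
  G <- do.call(rbind, lapply(individuals, function(i) unclass(i$genome)))
  list(mean_fitness = mean(fit),
       top_quartile = fit[top_i],
       bottom_quartile = fit[bot_i],
       genome_sd = apply(G, 2, stats::sd))
}

# random perfect matching of a vector holding each parent index twice,
# avoiding self-pairs when possible
pair_parents <- function(n_parents) {
  pool <- rep(seq_len(n_parents), each = 2L)
  for (try in 1:50) {
    perm <- sample(pool)
    pairs <- matrix(perm, ncol = 2, byrow = TRUE)
    if (n_parents == 1L || all(pairs[, 1] != pairs[, 2])) return(pairs)
  }
  pairs                                   # degenerate inputs may force self-pairs
}

#' Build the next generation's genomes
#'
#' Selects `n_parents` parents by roulette wheel; the parents' genomes pass
#' unchanged and the other half of the population is produced by crossing
#' the parents in random pairs (each parent used exactly twice), applying
#' one-point crossover followed by Gaussian mutation.
#'
#' @param individuals evaluated current generation.
#' @param cfg a [ga_config()].
#' @return list of `pop_size` genomes.
#' @export
next_generation <- function(individuals, cfg) {
  parents <- roulette_select(individuals, cfg$n_parents)
  pairs <- pair_parents(cfg$n_parents)
  offspring <- lapply(seq_len(nrow(pairs)), function(r) {
    child <- one_point_crossover(parents[[pairs[r, 1]]]$genome,
                                 parents[[pairs[r, 2]]]$genome)
    gaussian_mutation(child, cfg$mutation_variance)
  })
  c(lapply(parents, `[[`, "genome"), offspring)
}

#' Run a genetic algorithm over droplet formulations
#'
#' The generational driver: seeds an initial random population, evaluates
#' every individual `repeats` times in the scheduled arena, records
#' per-generation statistics and a flat evaluation log, and breeds each next
#' generation with [next_generation()]. Parents carried over are
#' re-evaluated in their new generation, as the physical platform re-ran
#' every individual.
#'
#' @param cfg a [ga_config()].
#' @param evaluator function `(genome, arena, seed) -> fitness`.
#' @param verbose print per-generation progress.
#' @return a `ga_run`: list with `config`, `generations` (each with `index`,
#'   `arena_id`, `individuals`, `stats`) and `evaluation_log` (data frame:
#'   one row per simulated experiment).
#' @export
run_ga <- function(cfg = ga_config(), evaluator, verbose = FALSE) {
  stopifnot(inherits(cfg, "ga_config"), is.function(evaluator))
  genomes <- with_seed(derive_seed(cfg$seed, 0L),
                       replicate(cfg$pop_size, random_genome(),
                                 simplify = FALSE))
  gens <- vector("list", cfg$generations)
  log_rows <- list()
  for (g in seq_len(cfg$generations)) {
    ar <- arena_for_generation(cfg, g)
    inds <- vector("list", cfg$pop_size)
    for (i in seq_len(cfg$pop_size)) {
      seeds <- vapply(seq_len(cfg$repeats),
                      function(r) derive_seed(cfg$seed, g, i, r), integer(1))
      inds[[i]] <- evaluate_individual(genomes[[i]], ar, cfg$repeats,
                                       evaluator, seeds)
      gm <- unname(unclass(genomes[[i]]))
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        generation = g, individual = i, repeat_idx = seq_len(cfg$repeats),
        octanol = gm[1], dep = gm[2], octanoic = gm[3], pentanol = gm[4],
        arena = ar$label, seed = seeds,
        fitness = inds[[i]]$repeat_fitnesses)
    }
    gens[[g]] <- list(index = g, arena_id = ar$label, individuals = inds,
                      stats = generation_stats(inds))
    if (verbose)
      message(sprintf("generation %d (%s): mean fitness %.2f",
                      g, ar$label, gens[[g]]$stats$mean_fitness))
    if (g < cfg$generations)
      genomes <- with_seed(derive_seed(cfg$seed, g, 0L, 0L),
                           next_generation(inds, cfg))
  }
  structure(list(config = cfg, generations = gens,
                 evaluation_log = do.call(rbind, log_rows)),
            class = "ga_run")
}

#' @export
print.ga_run <- function(x, ...) {
  mf <- vapply(x$generations, function(g) g$stats$mean_fitness, numeric(1))
  cat(sprintf("<ga_run> %d generations x %d individuals x %d repeats (%d experiments)\n",
              length(x$generations), x$config$pop_size, x$config$repeats,
              nrow(x$evaluation_log)))
  cat("mean fitness by generation:", paste(sprintf("%.2f", mf), collapse = " "), "\n")
  invisible(x)
}

#' Per-generation summary of a GA run
#'
#' @param object a `ga_run`.
#' @param ... unused.
#' @return data frame: generation, arena, mean/top-quartile/bottom-quartile
#'   fitness and per-component genome standard deviations.
#' @export
summary.ga_run <- function(object, ...) {
  do.call(rbind, lapply(object$generations, function(g) {
    s <- g$stats
    data.frame(generation = g$index, arena = g$arena_id,
               mean_fitness = s$mean_fitness, top_quartile = s$top_quartile,
               bottom_quartile = s$bottom_quartile,
               sd_octanol = s$genome_sd[["octanol"]],
               sd_dep = s$genome_sd[["dep"]],
               sd_octanoic = s$genome_sd[["octanoic"]],
               sd_pentanol = s$genome_sd[["pentanol"]])
  }))
}
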