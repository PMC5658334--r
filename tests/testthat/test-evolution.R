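test_that("evaluate_individual runs one experiment per repeat with distinct seeds", {
  calls <- new.env(); calls$seeds <- integer(0)
  ev <- function(g, a, s) { calls$seeds <- c(calls$seeds, s); 3 }
  ind <- evaluate_individual(genome(1, 0, 0, 0), make_empty_arena(), 5, ev, 11:15)
  expect_equal(length(calls$seeds), 5)
  expect_equal(calls$seeds, 11:15)
  expect_equal(ind$mean_fitness, 3)
  expect_equal(ind$repeat_fitnesses, rep(3, 5))

  # deterministic genome-only evaluator: zero variance across repeats
  ev2 <- function(g, a, s) sum(unclass(g) * 1:4)
  ind2 <- evaluate_individual(genome(0, 0, 0, 1), make_empty_arena(), 5, ev2, 1:5)
  expect_equal(sd(ind2$repeat_fitnesses), 0)

  evbad <- function(g, a, s) stop("camera offline")
  expect_error(
    evaluate_individual(genome(1, 0, 0, 0), make_empty_arena(), 2, evbad, 1:2),
    "camera offline")
})

test_that("generation statistics rank quartiles as the 5th and 15th of 20", {
  gs <- with_seed(2, replicate(20, random_genome(), simplify = FALSE))
  inds <- make_individuals(gs, 20:1)
  s <- generation_stats(inds)
  expect_equal(s$mean_fitness, mean(1:20))
  expect_equal(s$top_quartile, 16)        # 5th by descending fitness
  expect_equal(s$bottom_quartile, 6)      # 15th by descending fitness

  # constant fitness: all three statistics collapse to the constant
  indc <- make_individuals(gs, rep(4, 20))
  sc <- generation_stats(indc)
  expect_equal(unlist(sc[1:3], use.names = FALSE), rep(4, 3))

  # identical genomes: per-component SD is zero
  indsame <- make_individuals(rep(list(genome(0.25, 0.25, 0.25, 0.25)), 20),
                              rep(1, 20))
  expect_equal(unname(generation_stats(indsame)$genome_sd), rep(0, 4))
})

test_that("next_generation keeps 10 parents and breeds 10 offspring, each parent twice", {
  gs <- with_seed(4, replicate(20, random_genome(), simplify = FALSE))
  inds <- make_individuals(gs, runif(20, 1, 5))
  cfg <- ga_config(seed = 1)
  nxt <- with_seed(7, next_generation(inds, cfg))
  expect_length(nxt, 20)

  # with mutation off, the selected parents pass through unchanged
  cfg0 <- ga_config(seed = 1, mutation_variance = 0)
  parents <- with_seed(3, roulette_select(inds, 10))
  nxt0 <- with_seed(3, next_generation(inds, cfg0))
  for (i in 1:10)
    expect_identical(nxt0[[i]], parents[[i]]$genome)

  # pairing multiset: each parent appears exactly twice
  pairs <- with_seed(5, dropevo:::pair_parents(10))
  expect_equal(sort(tabulate(c(pairs), 10)), rep(2L, 10))
  expect_true(all(pairs[, 1] != pairs[, 2]))

  # forced self-pairing with zero mutation duplicates the parent
  one <- make_individuals(list(genome(0.4, 0.3, 0.2, 0.1)), 2)
  child <- with_seed(1, one_point_crossover(one[[1]]$genome, one[[1]]$genome))
  expect_identical(child, one[[1]]$genome)
})

test_that("a GA run logs generations x pop x repeats experiments with full stats", {
  cfg <- ga_config(generations = 10, pop_size = 20, repeats = 5, seed = 42)
  run <- run_ga(cfg, stub_evaluator(2))
  expect_s3_class(run, "ga_run")
  expect_length(run$generations, 10)
  expect_equal(nrow(run$evaluation_log), 10 * 20 * 5)   # 1000 experiments
  expect_equal(sum(!duplicated(run$evaluation_log[, c("generation", "individual")])),
               200)                                     # 200 evaluated individuals
  expect_true(all(run$evaluation_log$fitness == 2))
  s <- summary(run)
  expect_equal(nrow(s), 10)
  expect_true(all(s$arena == "empty"))
  # same seed reproduces the run exactly
  run2 <- run_ga(cfg, stub_evaluator(2))
  expect_identical(run$evaluation_log, run2$evaluation_log)
})

test_that("the arena schedule switches environments at the stated generations", {
  arenas <- list(make_empty_arena(), make_pillar_arena(), make_lsystem_arena())
  cfg <- ga_config(generations = 30, seed = 2,
                   arena_schedule = swap_schedule(arenas, 10))
  run <- run_ga(cfg, stub_evaluator(1))
  labs <- vapply(run$generations, function(g) g$arena_id, character(1))
  expect_equal(labs[10], "empty")
  expect_equal(labs[11], "pillars")       # first swap
  expect_equal(labs[20], "pillars")
  expect_equal(labs[21], "lsystem:7")     # second swap
  expect_error(ga_config(generations = 5, arena_schedule =
                           swap_schedule(arenas, 10)), "cover")
})

test_that("single-generation runs reproduce direct statistics of the random population", {
  cfg <- ga_config(generations = 1, seed = 9)
  ev <- function(g, a, s) 10 * g[["pentanol"]]
  run <- run_ga(cfg, ev)
  direct <- generation_stats(run$generations[[1]]$individuals)
  expect_equal(run$generations[[1]]$stats, direct)
})

test_that("fitness rises on a deterministic unimodal landscape in >= 9 of 10 seeds", {
  ev <- unimodal_evaluator()
  rises <- sapply(1:10, function(sd) {
    run <- run_ga(ga_config(generations = 10, pop_size = 20, repeats = 1,
                            seed = sd), ev)
    s <- summary(run)
    s$mean_fitness[10] > s$mean_fitness[1]
  })
  expect_gte(sum(rises), 9)
})
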