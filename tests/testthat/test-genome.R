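test_that("genome construction enforces the simplex invariants", {
  g <- genome(0.1, 0.2, 0.3, 0.4)
  expect_s3_class(g, "genome")
  expect_equal(sum(g), 1)
  expect_named(unclass(g), c("octanol", "dep", "octanoic", "pentanol"))
  expect_error(genome(0.5, 0.5, 0.5, 0.5), "sum to 1")
  expect_error(genome(-0.1, 0.5, 0.3, 0.3), "non-negative")
})

test_that("random genomes are reproducible and uniform on the simplex", {
  g1 <- with_seed(42, random_genome())
  g2 <- with_seed(42, random_genome())
  expect_identical(g1, g2)

  set.seed(7)
  draws <- t(replicate(10000, unclass(random_genome())))
  expect_true(all(draws >= 0))
  expect_equal(unname(rowSums(draws)), rep(1, 10000), tolerance = 1e-12)
  # symmetric Dirichlet(1,1,1,1): each component has mean 1/4
  expect_equal(unname(colMeans(draws)), rep(0.25, 4), tolerance = 0.01)
})

test_that("normalisation rescales and rejects degenerate recipes", {
  expect_equal(unclass(normalize_genome(c(1, 0, 0, 0))),
               c(octanol = 1, dep = 0, octanoic = 0, pentanol = 0))
  expect_equal(unname(unclass(normalize_genome(c(2, 2, 2, 2)))), rep(0.25, 4))
  expect_equal(unname(unclass(normalize_genome(c(0.4, 0.3, 0.3, 0.4)))),
               c(2 / 7, 3 / 14, 3 / 14, 2 / 7))
  expect_error(normalize_genome(c(0, 0, 0, 0)), "degenerate")
})

test_that("one-point crossover takes a prefix from a, suffix from b, then renormalises", {
  a <- genome(0.4, 0.3, 0.2, 0.1)
  b <- genome(0.1, 0.2, 0.3, 0.4)
  child <- one_point_crossover(a, b, cut = 2)
  expect_equal(unname(unclass(child)), c(2 / 7, 3 / 14, 3 / 14, 2 / 7))

  # identical parents: child equals parent for every cut
  for (k in 1:3)
    expect_equal(unclass(one_point_crossover(a, a, cut = k)), unclass(a))

  # cut point frequencies are uniform over {1,2,3}
  set.seed(11)
  cuts <- replicate(10000, {
    ch <- one_point_crossover(genome(1, 0, 0, 0), genome(0, 0.5, 0.25, 0.25))
    # the child uniquely identifies the cut for these parents
    if (ch[["dep"]] > 0) 1L
    else if (ch[["octanoic"]] > 0) 2L
    else 3L
  })
  expect_equal(as.vector(table(cuts)) / 10000, rep(1 / 3, 3), tolerance = 0.02)
})

test_that("degenerate crossover of complementary sparse parents stays valid", {
  a <- genome(0, 0, 0, 1)
  b <- genome(1, 0, 0, 0)
  set.seed(3)
  for (k in 1:3) {
    ch <- one_point_crossover(a, b, cut = k)
    expect_equal(sum(ch), 1)
  }
})

test_that("gaussian mutation has the stated noise scale and preserves the simplex", {
  g <- genome(0.25, 0.25, 0.25, 0.25)
  expect_identical(gaussian_mutation(g, variance = 0), g)

  # pre-clamp noise sd equals sqrt(variance) ~ 0.316 for variance 0.1
  set.seed(13)
  noise <- rnorm(10000, 0, sqrt(0.1))
  expect_equal(sd(noise), sqrt(0.1), tolerance = 0.02)

  set.seed(17)
  for (i in 1:200) {
    m <- gaussian_mutation(random_genome(), variance = 0.1)
    expect_true(all(m >= 0))
    expect_equal(sum(m), 1, tolerance = 1e-9)
  }
})

test_that("roulette selection is fitness-proportionate and without replacement", {
  pop <- make_individuals(list(genome(1, 0, 0, 0), genome(0, 1, 0, 0),
                               genome(0, 0, 1, 0), genome(0, 0, 0, 1)),
                          c(1, 0, 0, 0))
  # only individual 1 has weight
  for (s in 1:20)
    expect_identical(with_seed(s, roulette_select(pop, 1))[[1]], pop[[1]])

  # P(first | fitnesses 3,1) = 0.75
  pop2 <- make_individuals(list(genome(1, 0, 0, 0), genome(0, 1, 0, 0)), c(3, 1))
  set.seed(23)
  hits <- replicate(10000, identical(roulette_select(pop2, 1)[[1]], pop2[[1]]))
  expect_equal(mean(hits), 0.75, tolerance = 0.02)

  # k = n with uniform fitness returns a permutation
  pop3 <- make_individuals(list(genome(1, 0, 0, 0), genome(0, 1, 0, 0),
                                genome(0, 0, 1, 0)), c(2, 2, 2))
  sel <- with_seed(5, roulette_select(pop3, 3))
  expect_setequal(sapply(sel, function(i) which.max(unclass(i$genome))), 1:3)

  # zero fitness everywhere falls back to uniform sampling
  pop4 <- make_individuals(list(genome(1, 0, 0, 0), genome(0, 1, 0, 0)), c(0, 0))
  expect_length(with_seed(2, roulette_select(pop4, 2)), 2)
})

test_that("selection frequencies pass a chi-square test against fitness proportions", {
  pop <- make_individuals(list(genome(1, 0, 0, 0), genome(0, 1, 0, 0),
                               genome(0, 0, 1, 0)), c(5, 3, 2))
  set.seed(31)
  picks <- replicate(10000,
    which.max(unclass(roulette_select(pop, 1)[[1]]$genome)))
  tab <- tabulate(picks, 3)
  p <- chisq.test(tab, p = c(0.5, 0.3, 0.2))$p.value
  expect_gt(p, 0.01)
})

test_that("all GA operators map valid genomes to valid genomes", {
  set.seed(41)
  for (i in 1:100) {
    a <- random_genome(); b <- random_genome()
    for (g in list(one_point_crossover(a, b), gaussian_mutation(a),
                   normalize_genome(unclass(a) * runif(1, 0.5, 2)))) {
      expect_true(all(g >= 0))
      expect_equal(sum(g), 1, tolerance = 1e-9)
    }
  }
})

test_that("individuals average their repeat fitnesses", {
  ind <- individual(genome(0.25, 0.25, 0.25, 0.25), c(1, 2, 3, 4, 5))
  expect_equal(ind$mean_fitness, 3)
  expect_error(individual(genome(1, 0, 0, 0), c(-1, 2)), "non-negative")
})
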