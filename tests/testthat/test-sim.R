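test_that("the trait map is deterministic, continuous and chemically ordered", {
  g <- genome(0.1, 0.2, 0.3, 0.4)
  expect_identical(genome_to_traits(g), genome_to_traits(g))

  # pure DEP sinks: motility below the moving-detection threshold
  cfg <- sim_config()
  tr_dep <- genome_to_traits(genome(0, 1, 0, 0))
  expect_lt(tr_dep[["motility"]], cfg$static_eps)
  # pure pentanol is fast but unstable
  tr_pent <- genome_to_traits(genome(0, 0, 0, 1))
  expect_gt(tr_pent[["motility"]], 2)
  expect_lt(tr_pent[["stability"]], 0.5)

  # numeric Lipschitz check over sampled pairs
  set.seed(12)
  L <- 12   # conservative bound for the default coefficients
  for (i in 1:200) {
    g1 <- random_genome(); g2 <- random_genome()
    d_tr <- max(abs(genome_to_traits(g1) - genome_to_traits(g2)))
    d_g <- sqrt(sum((unclass(g1) - unclass(g2))^2))
    expect_lte(d_tr, L * d_g + 1e-12)
  }
})

test_that("simulated experiments have the right duration, injection count and determinism", {
  cfg <- small_sim_config()
  g <- genome(0.1, 0.1, 0.2, 0.6)
  sim <- simulate_experiment(g, make_empty_arena(), cfg, seed = 3)
  expect_length(sim$frames, cfg$duration * cfg$fps)
  expect_length(sim$counts, cfg$n_frames)
  expect_equal(nrow(sim$frames[[1]]), 5)            # five injected droplets
  expect_equal(sim$counts[1], 5)

  sim2 <- simulate_experiment(g, make_empty_arena(), cfg, seed = 3)
  expect_identical(sim$frames, sim2$frames)
  expect_identical(sim$counts, sim2$counts)

  # default configuration records 1800 frames
  expect_equal(sim_config()$n_frames, 1800L)
})

test_that("volume is conserved under splits and only dissolution removes it", {
  cfg <- small_sim_config()
  # high-division genome in the pillar arena, no dissolution (stable)
  g <- genome(0.2, 0, 0.5, 0.3)
  tr <- genome_to_traits(g)
  expect_equal(tr[["decay_rate"]], 0)
  sim <- simulate_experiment(g, make_pillar_arena(), cfg, seed = 8)
  vols <- vapply(sim$frames, function(f)
    sum((f[, "radius"] / cfg$lens_coef)^3), numeric(1))
  expect_equal(max(vols), 50, tolerance = 1e-9)     # never exceeds 5 x 10 ul
  expect_true(all(diff(round(vols, 9)) <= 1e-9))    # non-increasing
})

test_that("immotile droplets stay put and keep a static ground truth", {
  cfg <- small_sim_config(noise_amplitude = 0)
  sim <- simulate_experiment(genome(0, 1, 0, 0), make_empty_arena(), cfg, seed = 1)
  first <- sim$frames[[1]]; last <- sim$frames[[length(sim$frames)]]
  # initial contact relaxation may nudge them slightly; no sustained motion
  expect_lt(max(abs(last[, "x"] - first[, "x"])), 0.8)
  expect_lt(max(abs(last[, "y"] - first[, "y"])), 0.8)
  expect_equal(tail(sim$counts, 1), 0)              # all static at the end
})

test_that("droplets never penetrate pillars beyond the squeeze allowance", {
  cfg <- small_sim_config()
  a <- make_pillar_arena()
  sim <- simulate_experiment(genome(0.2, 0.1, 0.2, 0.5), a, cfg, seed = 5)
  p <- a$pillars
  for (f in sim$frames[seq(1, length(sim$frames), by = 10)]) {
    if (!nrow(f)) next
    D <- outer(f[, "x"], p$x, "-")^2 + outer(f[, "y"], p$y, "-")^2
    surf <- sqrt(D) - 1                    # distance to pillar surface
    r_eff <- cfg$squeeze_factor * f[, "radius"]
    expect_gte(min(sweep(surf, 1, r_eff, "-")), -0.35)
  }
})

test_that("rendered frames have static background and disc-area droplets", {
  cfg <- small_sim_config()
  a <- make_pillar_arena()
  bg <- render_background(a, cfg)
  expect_equal(dim(bg), c(cfg$height, cfg$width))
  # no agents: frame equals the background exactly (noise off)
  empty <- render_frame(matrix(numeric(0), 0, 6,
                               dimnames = list(NULL, c("id", "x", "y", "radius",
                                                       "state", "static_time"))),
                        a, cfg, bg = bg)
  expect_identical(empty, bg)

  # one droplet of radius r: connected blob of area ~ pi (r px)^2
  ag <- cbind(id = 1, x = 5, y = 5, radius = 1.5, state = 1, static_time = 0)
  img <- render_frame(ag, a, cfg, bg = bg)
  ndrop <- sum(img == 235 & bg != 235)
  r_px <- 1.5 * cfg$px_per_mm
  expect_equal(ndrop, pi * r_px^2, tolerance = 0.1 * pi * r_px^2)

  # pillar pixels identical across frames
  pil <- which(bg == 90)
  expect_identical(img[setdiff(pil, which(img == 235))],
                   bg[setdiff(pil, which(img == 235))])

  # byte-level reproducibility of the full rendered video
  g <- genome(0.1, 0.1, 0.2, 0.6)
  s1 <- simulate_experiment(g, a, cfg, seed = 2)
  s2 <- simulate_experiment(g, a, cfg, seed = 2)
  f1 <- frame_stream(s1); f2 <- frame_stream(s2)
  for (i in c(1, 50, 150)) expect_identical(f1(i), f2(i))
})

test_that("higher motility+division trait scores earn higher measured fitness", {
  cfg <- small_sim_config()
  ev <- ground_truth_evaluator(cfg)
  ea <- make_empty_arena()
  set.seed(20)
  gs <- replicate(30, random_genome(), simplify = FALSE)
  score <- sapply(gs, function(g) {
    tr <- genome_to_traits(g)
    tr[["motility"]] + 20 * tr[["division_rate"]]
  })
  fit <- sapply(seq_along(gs), function(i)
    mean(sapply(1:3, function(r) ev(gs[[i]], ea, derive_seed(77, i, r)))))
  expect_gt(cor(score, fit, method = "spearman"), 0.5)
})

test_that("the environment changes measured fitness for a fixed motile genome", {
  cfg <- small_sim_config()
  ev <- ground_truth_evaluator(cfg)
  g <- genome(0.1, 0.1, 0.2, 0.6)
  f_empty <- sapply(1:20, function(s) ev(g, make_empty_arena(), s))
  f_pill <- sapply(1:20, function(s) ev(g, make_pillar_arena(), s))
  expect_lt(t.test(f_empty, f_pill)$p.value, 0.05)
})
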