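# tiny synthetic videos with hard discs on a uniform background
disc_frame <- function(dim = c(200, 200), rows, cols, r = 8, bg = 50, fg = 200) {
  .draw <- getFromNamespace(".draw_discs_cpp", "dropevo")
  .draw(matrix(bg, dim[1], dim[2]), rows, cols, rep(r, length(rows)), fg)
}

orbit_video <- function(n_frames, n_discs = 1, stop_at = Inf, dim = c(200, 200),
                        r = 8, speed = 2 * pi / 100) {
  lapply(seq_len(n_frames), function(i) {
    t <- min(i, stop_at)
    ang <- speed * t + 2 * pi * (seq_len(n_discs) - 1) / max(n_discs, 1)
    disc_frame(dim, 100 + 60 * sin(ang), 100 + 60 * cos(ang), r = r)
  })
}

test_that("the circular ROI mask matches its analytic area and symmetry", {
  cfg <- vision_config(roi_radius = 275)
  m <- roi_mask(cfg, c(600, 800))
  expect_equal(sum(m), pi * 275^2, tolerance = 0.005 * pi * 275^2)
  expect_identical(m, m[rev(seq_len(600)), ])       # mirror symmetric
  expect_identical(m, m[, rev(seq_len(800))])
  expect_equal(sum(roi_mask(vision_config(roi_radius = 0), c(50, 50))), 0)
})

test_that("a constant video produces an empty foreground after burn-in", {
  cfg <- vision_config(roi_radius = 90, history_frames = 30)
  frames <- replicate(40, matrix(77, 200, 200), simplify = FALSE)
  model <- new_foreground_model(c(200L, 200L), cfg)
  for (f in frames) fg <- update_foreground(model, f)
  expect_equal(sum(fg), 0)
  expect_error(update_foreground(model, matrix(0, 10, 10)), "size")
})

test_that("a moving disc is segmented with IoU above 0.7", {
  cfg <- vision_config(roi_radius = 90, history_frames = 30, min_area = 10)
  frames <- orbit_video(60)
  model <- new_foreground_model(c(200L, 200L), cfg)
  for (i in seq_along(frames)) fg <- update_foreground(model, frames[[i]])
  truth <- frames[[60]] == 200
  iou <- sum(fg & truth) / sum(fg | truth)
  expect_gt(iou, 0.7)
})

test_that("a disc that stops is absorbed into the background within [2, 5] s", {
  cfg <- vision_config(roi_radius = 90, min_area = 10)   # default 90-frame history
  frames <- orbit_video(450, stop_at = 150)
  cnt <- counts_from_video(frames, cfg)
  expect_equal(cnt[140], 1)
  gone <- which(cnt[151:450] == 0)[1]
  latency <- gone / 30                                    # 30 fps video
  expect_gte(latency, 2); expect_lte(latency, 5)
})

test_that("find_droplets reports one 8-connected component per blob", {
  m <- matrix(FALSE, 60, 60)
  expect_equal(nrow(find_droplets(m, 1)), 0)

  mask <- disc_frame(c(60, 60), c(15, 45), c(15, 45), r = 6) == 200
  d <- find_droplets(mask, min_area = 5)
  d <- d[order(d$row), ]
  expect_equal(nrow(d), 2)
  expect_equal(d$row, c(15, 45), tolerance = 1)
  expect_equal(d$col, c(15, 45), tolerance = 1)
  expect_equal(d$area, rep(sum(mask) / 2, 2), tolerance = 3)

  # a one-pixel diagonal gap keeps components joined under 8-connectivity,
  # a clean column gap separates them
  m2 <- matrix(FALSE, 10, 10); m2[2:4, 2:4] <- TRUE; m2[5, 5] <- TRUE
  expect_equal(nrow(find_droplets(m2, 1)), 1)
  m3 <- matrix(FALSE, 10, 10); m3[2:4, 2:4] <- TRUE; m3[2:4, 6:8] <- TRUE
  expect_equal(nrow(find_droplets(m3, 1)), 2)

  # min_area filters small blobs
  expect_equal(nrow(find_droplets(m2, 50)), 0)

  # contours are closed paths around each blob
  d4 <- find_droplets(mask, min_area = 5, contours = TRUE)
  for (ctr in d4$contour) {
    expect_identical(ctr[1, ], ctr[nrow(ctr), ])
    expect_true(all(mask[ctr]))
  }
})

test_that("detection merging unifies nearby fragments only", {
  d <- data.frame(id = 1:3, row = c(10, 14, 40), col = c(10, 12, 40),
                  area = c(20, 10, 30))
  m <- merge_detections(d, merge_dist = 6)
  expect_equal(nrow(m), 2)
  expect_equal(sort(m$area), c(30, 30))
  expect_identical(merge_detections(d, 0), d)
})

test_that("final-frame counts are exact on well-separated synthetic videos", {
  cfg <- vision_config(roi_radius = 90, history_frames = 30, min_area = 10)
  set.seed(33)
  correct <- sapply(1:50, function(k) {
    n <- sample(0:4, 1)
    frames <- orbit_video(45, n_discs = n)
    if (n == 0) frames <- replicate(45, disc_frame(c(200, 200), numeric(0),
                                                   numeric(0)), simplify = FALSE)
    fitness_from_video(frames, cfg) == n
  })
  expect_gte(mean(correct), 0.95)
})

test_that("video fitness matches the stated counting semantics", {
  cfg <- vision_config(roi_radius = 90, history_frames = 30, min_area = 10)
  # moving throughout: all discs counted at the final frame
  expect_equal(fitness_from_video(orbit_video(60, n_discs = 3), cfg), 3)
  expect_error(fitness_from_video(list(), cfg), "empty")
})

test_that("the full pipeline tracks simulator ground truth and is deterministic", {
  scfg <- small_sim_config()
  vcfg <- vision_config_for_sim(scfg)
  ea <- make_empty_arena()
  set.seed(5)
  diffs <- sapply(1:12, function(k) {
    g <- random_genome()
    sim <- simulate_experiment(g, ea, scfg, seed = 100 + k)
    fitness_from_video(frame_stream(sim), vcfg) - tail(sim$counts, 1)
  })
  # most recipes agree within one droplet; recipes near the propulsion onset
  # can fragment (see the methods vignette)
  expect_gte(mean(abs(diffs) <= 1), 0.6)
  expect_lte(median(abs(diffs)), 1)

  # immotile recipe scores zero
  f0 <- evaluate_genome(genome(0, 1, 0, 0), ea, seed = 1, sim_cfg = scfg)
  expect_equal(f0, 0)

  # deterministic end to end
  g <- genome(0.1, 0.1, 0.2, 0.6)
  expect_identical(evaluate_genome(g, ea, 7, scfg),
                   evaluate_genome(g, ea, 7, scfg))
})

test_that("fitness respects the volume-conservation upper bound", {
  scfg <- small_sim_config()
  vcfg <- vision_config_for_sim(scfg)
  # max splits: volume halves until below min_volume (10 -> 1.25: 3 splits)
  bound <- scfg$n_droplets * 2^3
  set.seed(9)
  for (k in 1:4) {
    g <- random_genome()
    f <- evaluate_genome(g, make_pillar_arena(), seed = k, sim_cfg = scfg,
                         vision_cfg = vcfg)
    expect_gte(f, 0); expect_lte(f, bound)
  }
})
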