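#' Vision pipeline configuration
#'
#' Parameters of the droplet-detection pipeline: the circular region of
#' interest overlapping the dish, and the per-pixel mixture-of-Gaussians
#' (MoG) background model whose short memory absorbs any object static for
#' roughly 3 s into the background.
#'
#' @param roi_center `(col, row)` pixel centre of the ROI; `NULL` = image
#'   centre.
#' @param roi_radius ROI radius in px (default 275).
#' @param history_frames background memory in frames (default 90, i.e. 3 s at
#'   30 fps); the learning rate is `1/history_frames`.
#' @param n_gaussians mixture components per pixel.
#' @param variance_threshold squared-Mahalanobis match threshold (2.5^2).
#' @param background_ratio cumulative-weight fraction defining the background
#'   component set; together with the learning rate it sets the ~3 s
#'   absorption latency of stopped objects.
#' @param init_var initial variance of a newly seeded component.
#' @param min_var variance floor.
#' @param min_area minimum blob area kept by [find_droplets()], px^2.
#' @param merge_dist blobs whose centroids lie within this distance (px) are
#'   merged into one detection (fragments of a partially absorbed droplet);
#'   0 disables merging.
#' @return a `vision_config` list.
#' @export
vision_config <- function(roi_center = NULL, roi_radius = 275,
                          history_frames = 90, n_gaussians = 5,
                          variance_threshold = 6.25, background_ratio = 0.4,
                          init_var = 100, min_var = 4, min_area = 20,
                          merge_dist = 0) {
  stopifnot(roi_radius >= 0, history_frames >= 1, n_gaussians >= 1)
  structure(list(roi_center = roi_center, roi_radius = roi_radius,
                 history_frames = history_frames, n_gaussians = n_gaussians,
                 variance_threshold = variance_threshold,
                 background_ratio = background_ratio,
                 learning_rate = 1 / history_frames,
                 init_var = init_var, min_var = min_var, min_area = min_area,
                 merge_dist = merge_dist),
            class = "vision_config")
}

#' Circular region-of-interest mask
#'
#' Only pixels inside the disc overlapping the experimental dish are
#' considered by the pipeline.
#'
#' @param cfg a [vision_config()].
#' @param dim image dimensions `c(rows, cols)`.
#' @return logical matrix, `TRUE` inside the ROI disc.
#' @export
roi_mask <- function(cfg, dim) {
  h <- dim[1]; w <- dim[2]
  ctr <- cfg$roi_center %||% c((w + 1) / 2, (h + 1) / 2)   # (col, row)
  dr2 <- (seq_len(h) - ctr[2])^2
  dc2 <- (seq_len(w) - ctr[1])^2
  outer(dr2, dc2, "+") <= cfg$roi_radius^2
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Create a fresh per-pixel MoG background model
#'
#' The model is reinitialised before each experiment; only pixels inside the
#' ROI carry mixture state.
#'
#' @param dim frame dimensions `c(rows, cols)`.
#' @param cfg a [vision_config()].
#' @return a `foreground_model` (environment holding the mixture state).
#' @export
new_foreground_model <- function(dim, cfg = vision_config()) {
  mask <- roi_mask(cfg, dim)
  idx <- which(mask)
  K <- cfg$n_gaussians
  m <- new.env(parent = emptyenv())
  m$dim <- dim; m$cfg <- cfg; m$roi_idx <- idx; m$roi <- mask
  m$w <- matrix(0, length(idx), K)
  m$mu <- matrix(0, length(idx), K)
  m$var <- matrix(cfg$init_var, length(idx), K)
  class(m) <- "foreground_model"
  m
}

#' Update the background model with one frame
#'
#' Classifies every ROI pixel as foreground/background against its Gaussian
#' mixture and updates the mixture online, so that an object that stays
#' static for about the history window is absorbed into the background.
#'
#' @param model a [new_foreground_model()].
#' @param frame numeric intensity matrix matching the model dimensions.
#' @return logical foreground mask (full frame; `FALSE` outside the ROI).
#' @export
update_foreground <- function(model, frame) {
  if (!identical(dim(frame), as.integer(model$dim)) &&
      !identical(dim(frame), model$dim))
    stop("frame size does not match the model")
  cfg <- model$cfg
  fgv <- .mog_update_cpp(model$w, model$mu, model$var,
                         as.numeric(frame[model$roi_idx]),
                         cfg$learning_rate, cfg$variance_threshold,
                         cfg$background_ratio, cfg$init_var, cfg$min_var)
  fg <- matrix(FALSE, model$dim[1], model$dim[2])
  fg[model$roi_idx] <- fgv
  fg
}

#' Detect droplets in a foreground mask
#'
#' Extracts 8-connected foreground components of at least `min_area` pixels
#' and describes each by its centroid, area and (optionally) closed boundary
#' contour.
#'
#' @param mask logical foreground matrix.
#' @param min_area minimum component area in px^2.
#' @param contours if `TRUE`, attach the traced boundary path of each blob.
#' @return data frame with columns `id`, `row`, `col`, `area` (one row per
#'   detected droplet); with `contours = TRUE` also a list column `contour`
#'   of `(row, col)` matrices.
#' @export
find_droplets <- function(mask, min_area = 20, contours = FALSE) {
  lab <- .label8_cpp(mask)
  n <- attr(lab, "n")
  if (n == 0L)
    return(data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                      area = numeric(0)))
  pix <- which(lab > 0)
  lv <- lab[pix]
  area <- tabulate(lv, nbins = n)
  rows <- ((pix - 1) %% nrow(mask)) + 1
  cols <- ((pix - 1) %/% nrow(mask)) + 1
  cr <- rowsum(rows, lv) / area
  cc <- rowsum(cols, lv) / area
  keep <- which(area >= min_area)
  out <- data.frame(id = seq_along(keep), row = cr[keep], col = cc[keep],
                    area = area[keep])
  if (contours)
    out$contour <- lapply(keep, function(k) .trace_boundary_cpp(lab, k))
  out
}

#' Merge nearby detections
#'
#' Single-linkage clustering of blob centroids: blobs closer than
#' `merge_dist` belong to one droplet (a partially background-absorbed
#' droplet can surface as several foreground fragments). Areas add;
#' centroids combine area-weighted.
#'
#' @param d detection data frame from [find_droplets()].
#' @param merge_dist linkage distance in px; <= 0 returns `d` unchanged.
#' @return merged detection data frame.
#' @export
merge_detections <- function(d, merge_dist) {
  if (merge_dist <= 0 || nrow(d) < 2L) return(d)
  hc <- stats::hclust(stats::dist(d[, c("row", "col")]), method = "single")
  grp <- stats::cutree(hc, h = merge_dist)
  out <- do.call(rbind, lapply(split(d, grp), function(s)
    data.frame(row = sum(s$row * s$area) / sum(s$area),
               col = sum(s$col * s$area) / sum(s$area),
               area = sum(s$area))))
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("id", "row", "col", "area")]
}

detect_in_mask <- function(mask, cfg) {
  merge_detections(find_droplets(mask, cfg$min_area), cfg$merge_dist)
}

resolve_frames <- function(frames) {
  if (is.function(frames)) {
    n <- attr(frames, "n_frames")
    if (is.null(n)) stop("frame function needs an 'n_frames' attribute")
    list(get = frames, n = n)
  } else if (is.list(frames)) {
    list(get = function(i) frames[[i]], n = length(frames))
  } else stop("frames must be a list of matrices or a frame function")
}

#' Per-frame droplet counts of a video
#'
#' Streams all frames through a fresh background model and counts detected
#' droplets per frame.
#'
#' @param frames list of intensity matrices, or a frame function as returned
#'   by [frame_stream()].
#' @param cfg a [vision_config()].
#' @return integer vector of per-frame counts.
#' @export
counts_from_video <- function(frames, cfg = vision_config()) {
  fs <- resolve_frames(frames)
  if (fs$n < 1L) stop("empty frame stream")
  f1 <- fs$get(1)
  model <- new_foreground_model(dim(f1), cfg)
  counts <- integer(fs$n)
  for (i in seq_len(fs$n)) {
    fg <- update_foreground(model, if (i == 1L) f1 else fs$get(i))
    counts[i] <- nrow(detect_in_mask(fg, cfg))
  }
  counts
}

#' Fitness of a video: droplets detected in the final frame
#'
#' The fitness function of the evolutionary platform: stream the whole video
#' through the background model and return the number of droplets detected
#' in the last frame (frame 1800 for the standard 60 s, 30 fps recording).
#' Droplets static for roughly 3 s have been absorbed into the background by
#' then and are not counted.
#'
#' @inheritParams counts_from_video
#' @return non-negative integer count.
#' @export
fitness_from_video <- function(frames, cfg = vision_config()) {
  fs <- resolve_frames(frames)
  if (fs$n < 1L) stop("empty frame stream")
  f1 <- fs$get(1)
  model <- new_foreground_model(dim(f1), cfg)
  fg <- update_foreground(model, f1)
  if (fs$n > 1L)
    for (i in 2:fs$n) fg <- update_foreground(model, fs$get(i))
  nrow(detect_in_mask(fg, cfg))
}

#' Vision configuration matched to a simulation configuration
#'
#' Derives the ROI (dish radius at the rendering scale, image centre), the
#' history window (3 s at the simulated frame rate) and the
#' fragment-merging distance (0.6 injected-droplet diameters) from a
#' [sim_config()].
#'
#' @param sim_cfg a [sim_config()].
#' @param arena_radius dish radius in mm.
#' @param ... overrides passed to [vision_config()].
#' @return a `vision_config`.
#' @export
vision_config_for_sim <- function(sim_cfg, arena_radius = 27.5, ...) {
  dia_px <- 2 * sim_cfg$lens_coef * sim_cfg$droplet_volume^(1/3) *
    sim_cfg$px_per_mm
  vision_config(roi_radius = arena_radius * sim_cfg$px_per_mm,
                history_frames = max(2L, as.integer(round(3 * sim_cfg$fps))),
                merge_dist = 0.6 * dia_px, ...)
}

#' Evaluate a genome in an arena through the full pipeline
#'
#' The evaluator injected into the genetic algorithm: simulate the
#' experiment, render its video and measure fitness with the vision
#' pipeline. Deterministic given `(genome, arena, seed)`.
#'
#' @param g a [genome()].
#' @param arena an [arena()].
#' @param seed integer seed for the simulated experiment.
#' @param sim_cfg a [sim_config()].
#' @param vision_cfg a [vision_config()]; derived from `sim_cfg` if `NULL`.
#' @return non-negative fitness (final-frame droplet count).
#' @export
evaluate_genome <- function(g, arena, seed, sim_cfg = sim_config(),
                            vision_cfg = NULL) {
  if (is.null(vision_cfg))
    vision_cfg <- vision_config_for_sim(sim_cfg, arena$radius)
  sim <- simulate_experiment(g, arena, sim_cfg, seed)
  fitness_from_video(frame_stream(sim), vision_cfg)
}

#' Evaluator factories for the genetic algorithm
#'
#' `vision_evaluator()` returns the full simulate-render-detect pipeline;
#' `ground_truth_evaluator()` returns the simulator's own trailing-window
#' moving count at the final frame (the quantity the vision pipeline
#' estimates), which is much faster and is useful for large property studies.
#'
#' @param sim_cfg a [sim_config()].
#' @param vision_cfg optional [vision_config()] for the vision route.
#' @return a function `(genome, arena, seed) -> fitness`.
#' @export
vision_evaluator <- function(sim_cfg = sim_config(), vision_cfg = NULL) {
  function(g, arena, seed) evaluate_genome(g, arena, seed, sim_cfg, vision_cfg)
}

#' @rdname vision_evaluator
#' @export
ground_truth_evaluator <- function(sim_cfg = sim_config()) {
  function(g, arena, seed) {
    sim <- simulate_experiment(g, arena, sim_cfg, seed)
    sim$counts[length(sim$counts)]
  }
}
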