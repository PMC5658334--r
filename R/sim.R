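#' Default genome-to-trait mapping coefficients
#'
#' The droplet system has no quantitative physical model, so the simulator
#' maps a formulation genome to behavioural traits through a smooth
#' phenomenological map whose coefficients live here. The qualitative
#' directions follow the chemistry: 1-pentanol and 1-octanol (high aqueous
#' solubility, Marangoni-active) drive self-propulsion; DEP is dense and
#' viscous and suppresses it; octanoic acid promotes division; pentanol
#' excess destabilises droplets; DEP and octanoic acid make droplets prone to
#' hooking onto pillars.
#'
#' @return named list of coefficients (see the methods vignette for the
#'   functional form and units).
#' @export
trait_map_params <- function() {
  list(
    mot_pentanol = 3.5,   # mm/s at pure pentanol
    mot_octanol  = 2.0,
    mot_octanoic = 0.5,
    div_octanoic = 0.035, # 1/s division hazard at pure octanoic acid
    div_motility = 0.004, # 1/s per mm/s of motility
    stab_pent_onset = 0.4,   # pentanol fraction where stability starts to fall
    stab_pent_slope = 1.6,
    mot_onset     = 1.0,  # mm/s: Marangoni propulsion onset (sigmoid midpoint)
    mot_sharp     = 0.03, # mm/s: width of the onset (sharp: weak propulsion stalls)
    attr_base     = 0.25, # baseline pillar affinity, all recipes
    attr_dep      = 0.55,
    attr_octanoic = 0.2,
    decay_max     = 0.25  # 1/s dissolution hazard for a fully unstable hooked droplet
  )
}

#' Map a formulation genome to behavioural traits
#'
#' Deterministic, smooth (Lipschitz) map from the oil-fraction simplex to the
#' simulator's trait vector: `motility` (mm/s), `division_rate` (1/s
#' spontaneous division hazard, boosted at pillar impacts), `stability` and
#' `attraction` (dimensionless, in `[0, 1]`) and `decay_rate` (1/s
#' dissolution hazard while hooked or trapped).
#'
#' @param g a [genome()].
#' @param params coefficient list, see [trait_map_params()].
#' @return named numeric trait vector.
#' @export
genome_to_traits <- function(g, params = trait_map_params()) {
  g <- as_genome(g)
  p <- params
  raw_mot <- p$mot_pentanol * g[["pentanol"]] + p$mot_octanol * g[["octanol"]] +
    p$mot_octanoic * g[["octanoic"]]
  # self-propulsion switches on over a threshold, as Marangoni flows do:
  # weakly propelled recipes sit essentially still
  motility <- raw_mot / (1 + exp(-(raw_mot - p$mot_onset) / p$mot_sharp))
  division <- p$div_octanoic * g[["octanoic"]] + p$div_motility * motility
  stability <- min(1, max(0, 1 - p$stab_pent_slope *
                            max(0, g[["pentanol"]] - p$stab_pent_onset)))
  attraction <- min(1, p$attr_base + p$attr_dep * g[["dep"]] +
                      p$attr_octanoic * g[["octanoic"]])
  decay <- p$decay_max * (1 - stability)
  c(motility = unname(motility), division_rate = unname(division),
    stability = unname(stability), attraction = unname(attraction),
    decay_rate = unname(decay))
}

#' Simulation configuration
#'
#' Parameters of a simulated droplet experiment: the injection protocol
#' (5 droplets of 10 ul), the recording geometry (60 s at 30 fps, 800 x 600
#' frames, 10 px/mm) and the dynamics constants of the agent model.
#'
#' @param n_droplets droplets injected at the start.
#' @param droplet_volume injected volume per droplet, ul.
#' @param duration experiment length, s.
#' @param fps frames per second; the time step is `1/fps`.
#' @param width,height rendered frame size in px.
#' @param px_per_mm rendering scale.
#' @param noise_amplitude translational velocity noise, mm/s.
#' @param rot_diffusion rotational diffusion of the heading, rad^2/s.
#' @param static_eps speed below which a droplet counts as static, mm/s.
#' @param attract_range distance from a pillar surface within which hooking
#'   can occur, mm.
#' @param hook_rate hooking hazard scale, 1/s.
#' @param hold_scale mean hooked holding time scale, s (scaled by stability:
#'   stable droplets unhook sooner, see vignette).
#' @param split_speed minimum impact speed for a pillar-induced split, mm/s.
#' @param impact_split_scale seconds-equivalent of division hazard released
#'   by one pillar impact (split probability per fresh contact =
#'   `division_rate * impact_split_scale`).
#' @param split_refractory minimum time between successive divisions of one
#'   droplet, s.
#' @param static_dist displacement over the trailing `static_window` below
#'   which a droplet counts as static in the ground truth, mm.
#' @param trap_threshold stability below which a hooked droplet is trapped
#'   (never unhooks, dissolves at its decay rate).
#' @param min_volume splits stop when a daughter would fall below this, ul.
#' @param squeeze_factor deformability: the effective collision radius
#'   against pillars is `squeeze_factor * radius`, letting droplets squeeze
#'   through gaps narrower than their resting diameter.
#' @param lens_coef droplet radius = `lens_coef * volume^(1/3)` (mm per ul^(1/3)).
#' @param static_window trailing window defining the ground-truth "moving"
#'   count, s.
#' @param trait_params coefficients for [genome_to_traits()].
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_droplets = 5, droplet_volume = 10, duration = 60,
                       fps = 30, width = 800, height = 600, px_per_mm = 10,
                       noise_amplitude = 0.3, rot_diffusion = 0.6,
                       static_eps = 0.8, attract_range = 1.0, hook_rate = 0.6,
                       hold_scale = 4, split_speed = 1.0,
                       impact_split_scale = 1.5, trap_threshold = 0.5,
                       split_refractory = 1.5, min_volume = 1.25,
                       squeeze_factor = 0.35,
                       lens_coef = 0.7, static_window = 3, static_dist = 1.5,
                       trait_params = trait_map_params()) {
  n_frames <- duration * fps
  if (abs(n_frames - round(n_frames)) > 1e-9)
    stop("duration * fps must be an integer number of frames")
  structure(list(n_droplets = n_droplets, droplet_volume = droplet_volume,
                 duration = duration, fps = fps, dt = 1 / fps,
                 n_frames = as.integer(round(n_frames)),
                 width = width, height = height, px_per_mm = px_per_mm,
                 noise_amplitude = noise_amplitude, rot_diffusion = rot_diffusion,
                 static_eps = static_eps, attract_range = attract_range,
                 hook_rate = hook_rate, hold_scale = hold_scale,
                 split_speed = split_speed,
                 impact_split_scale = impact_split_scale,
                 trap_threshold = trap_threshold,
                 split_refractory = split_refractory, min_volume = min_volume,
                 squeeze_factor = squeeze_factor, lens_coef = lens_coef, static_window = static_window,
                 static_dist = static_dist,
                 trait_params = trait_params),
            class = "sim_config")
}

droplet_radius <- function(volume, cfg) cfg$lens_coef * volume^(1/3)

# agent state codes
ST_MOVING <- 1L; ST_HOOKED <- 2L; ST_TRAPPED <- 3L; ST_DISSOLVED <- 4L

new_agents <- function(n, cfg, arena) {
  inlet <- c(0, -0.8 * arena$radius)
  r <- droplet_radius(rep(cfg$droplet_volume, n), cfg)
  # sequential injections fan out on an arc above the inlet, spaced so the
  # droplets start essentially in contact but not overlapping
  arc <- 1.05 * 2 * r[1] / (2 * sin(pi / (2 * max(n - 1, 1))))
  ang <- seq(0, pi, length.out = max(n, 2))[seq_len(n)]
  x <- inlet[1] + arc * cos(ang) + rnorm(n, 0, 0.3)
  y <- inlet[2] + arc * abs(sin(ang)) + rnorm(n, 0, 0.3)
  # keep injection jitter inside the dish
  d <- sqrt(x^2 + y^2); lim <- arena$radius - r - 0.1
  scl <- ifelse(d > lim, lim / d, 1)
  list(x = x * scl, y = y * scl,
       theta = runif(n, 0, 2 * pi),
       volume = rep(cfg$droplet_volume, n), radius = r,
       static_time = numeric(n), state = rep(ST_MOVING, n),
       hook_until = rep(Inf, n), contact = rep(FALSE, n),
       split_ok_at = numeric(n))
}

#' Advance droplet agents by one time step
#'
#' One step of the phenomenological droplet model: active-Brownian
#' self-propulsion (constant speed set by the genome's motility, rotational
#' diffusion of the heading, translational noise), soft-disc droplet-droplet
#' repulsion, specular reflection at the dish boundary and at pillar
#' surfaces, division into volume-halving daughters (a spontaneous hazard,
#' boosted on pillar impacts above the split speed), hooking near pillars
#' with an exponential holding time (low-stability droplets become trapped
#' instead), and dissolution of hooked/trapped droplets at the genome's
#' decay rate. Uses the global RNG.
#'
#' @param st agent state list (internal layout; see [simulate_experiment()]).
#' @param arena an [arena()].
#' @param traits trait vector from [genome_to_traits()].
#' @param dt time step, s.
#' @param cfg a [sim_config()].
#' @param t current simulation time, s.
#' @return the updated agent state list.
#' @export
step_droplets <- function(st, arena, traits, dt, cfg, t = 0) {
  act <- which(st$state != ST_DISSOLVED)
  if (!length(act)) return(st)
  mot <- traits[["motility"]]

  # unhook when the holding time expires (trapped droplets never do)
  unhook <- act[st$state[act] == ST_HOOKED & t >= st$hook_until[act]]
  if (length(unhook)) {
    st$state[unhook] <- ST_MOVING
    st$theta[unhook] <- runif(length(unhook), 0, 2 * pi)
    st$hook_until[unhook] <- Inf
  }

  mv <- act[st$state[act] == ST_MOVING]
  if (length(mv)) {
    st$theta[mv] <- st$theta[mv] +
      rnorm(length(mv), 0, sqrt(2 * cfg$rot_diffusion * dt))
    # velocity fluctuations come from the propulsion flow itself; a stalled
    # droplet is pinned by its meniscus and sits truly still
    namp <- cfg$noise_amplitude * min(1, mot)
    vx <- mot * cos(st$theta[mv]) + rnorm(length(mv), 0, namp)
    vy <- mot * sin(st$theta[mv]) + rnorm(length(mv), 0, namp)
    st$x[mv] <- st$x[mv] + vx * dt
    st$y[mv] <- st$y[mv] + vy * dt
  }

  # soft-disc repulsion between droplets (surfactant-stabilised, no coalescence)
  act <- which(st$state != ST_DISSOLVED)
  if (length(act) > 1L) {
    for (ii in seq_along(act)[-length(act)]) {
      i <- act[ii]
      js <- act[(ii + 1L):length(act)]
      dx <- st$x[js] - st$x[i]; dy <- st$y[js] - st$y[i]
      dd <- sqrt(dx^2 + dy^2)
      ov <- st$radius[i] + st$radius[js] - dd
      for (k in which(ov > 0)) {
        j <- js[k]
        d0 <- max(dd[k], 1e-6)
        ux <- dx[k] / d0; uy <- dy[k] / d0
        # relax overlaps at a bounded speed so resting contacts stay visually
        # still instead of jittering frame to frame
        sh <- min(ov[k] / 2, 2 * dt)
        st$x[i] <- st$x[i] - ux * sh; st$y[i] <- st$y[i] - uy * sh
        st$x[j] <- st$x[j] + ux * sh; st$y[j] <- st$y[j] + uy * sh
      }
    }
  }

  # dish boundary: clamp inside and reflect the heading
  d <- sqrt(st$x[act]^2 + st$y[act]^2)
  for (i in act[d + st$radius[act] > arena$radius]) {
    phi <- atan2(st$y[i], st$x[i])
    lim <- arena$radius - st$radius[i]
    st$x[i] <- lim * cos(phi); st$y[i] <- lim * sin(phi)
    st$theta[i] <- reflect_heading(st$theta[i], phi + pi)  # inward normal
  }

  split_parent <- integer(0)

  # pillar interactions: reflect, maybe split, maybe hook
  np <- nrow(arena$pillars)
  mvi <- which(st$state == ST_MOVING)
  if (np && length(mvi)) {
    px <- arena$pillars$x; py <- arena$pillars$y
    pr <- arena$pillars$diameter / 2
    DX <- outer(st$x[mvi], px, "-"); DY <- outer(st$y[mvi], py, "-")
    SURF <- sweep(sqrt(DX^2 + DY^2), 2, pr, "-")   # distance to pillar surface
    j <- max.col(-SURF, ties.method = "first")     # nearest pillar per agent
    sel <- cbind(seq_along(mvi), j)
    r_eff <- cfg$squeeze_factor * st$radius[mvi]   # deformable against pillars
    gap <- SURF[sel] - r_eff
    ux <- DX[sel] / pmax(SURF[sel] + pr[j], 1e-6)
    uy <- DY[sel] / pmax(SURF[sel] + pr[j], 1e-6)

    hit <- which(gap < 0)
    was_contact <- st$contact[mvi]
    st$contact[mvi] <- FALSE
    st$contact[mvi[hit]] <- TRUE
    for (k in hit) {                       # impact: push out, reflect
      i <- mvi[k]
      lim <- pr[j[k]] + r_eff[k]
      st$x[i] <- px[j[k]] + ux[k] * lim
      st$y[i] <- py[j[k]] + uy[k] * lim
      st$theta[i] <- reflect_heading(st$theta[i], atan2(uy[k], ux[k]))
      # a fresh contact above the split speed may divide the droplet
      if (!was_contact[k] && mot > cfg$split_speed &&
          t >= st$split_ok_at[i] &&
          st$volume[i] / 2 >= cfg$min_volume &&
          runif(1) < traits[["division_rate"]] * cfg$impact_split_scale)
        split_parent <- c(split_parent, i)
    }

    near <- which(gap < cfg$attract_range)  # in or near contact
    if (length(near)) {
      i <- mvi[near]
      drift <- which(gap[near] >= 0)        # drift toward the pillar surface
      if (length(drift)) {
        id <- i[drift]
        pull <- 0.5 * traits[["attraction"]] * mot * dt
        st$x[id] <- st$x[id] - pull * ux[near[drift]]
        st$y[id] <- st$y[id] - pull * uy[near[drift]]
      }
      hooks <- i[runif(length(i)) < traits[["attraction"]] * cfg$hook_rate * dt]
      if (length(hooks)) {
        if (traits[["stability"]] < cfg$trap_threshold) {
          st$state[hooks] <- ST_TRAPPED
          st$hook_until[hooks] <- Inf
        } else {
          st$state[hooks] <- ST_HOOKED
          hold <- cfg$hold_scale * (2 - traits[["stability"]])
          st$hook_until[hooks] <- t + stats::rexp(length(hooks), rate = 1 / hold)
        }
      }
    }

    # hooked or trapped droplets dissolve at the genome's decay rate
    hk <- which(st$state %in% c(ST_HOOKED, ST_TRAPPED))
    if (length(hk)) {
      die <- hk[runif(length(hk)) < traits[["decay_rate"]] * dt]
      st$state[die] <- ST_DISSOLVED
    }
  }

  # spontaneous division of moving droplets
  mvi <- which(st$state == ST_MOVING)
  if (length(mvi)) {
    can <- mvi[st$volume[mvi] / 2 >= cfg$min_volume & t >= st$split_ok_at[mvi]]
    spont <- can[runif(length(can)) < traits[["division_rate"]] * dt]
    split_parent <- union(split_parent, spont)
  }
  for (i in split_parent) st <- split_agent(st, i, cfg, t)

  # static-time bookkeeping: hooked, trapped or sub-threshold droplets accumulate
  act <- which(st$state != ST_DISSOLVED)
  slow <- st$state[act] != ST_MOVING | mot < cfg$static_eps
  st$static_time[act] <- ifelse(slow, st$static_time[act] + dt, 0)
  st
}

reflect_heading <- function(theta, normal_angle) {
  # specular reflection of direction theta about the surface with this normal
  u <- c(cos(theta), sin(theta))
  n <- c(cos(normal_angle), sin(normal_angle))
  v <- u - 2 * sum(u * n) * n
  atan2(v[2], v[1])
}

split_agent <- function(st, i, cfg, t = 0) {
  v2 <- st$volume[i] / 2
  r2 <- droplet_radius(v2, cfg)
  perp <- st$theta[i] + pi / 2
  off <- r2 * 1.05
  n <- length(st$x) + 1L
  for (f in names(st)) st[[f]] <- c(st[[f]], st[[f]][i])
  st$volume[c(i, n)] <- v2
  st$radius[c(i, n)] <- r2
  st$x[i] <- st$x[i] + off * cos(perp); st$y[i] <- st$y[i] + off * sin(perp)
  st$x[n] <- st$x[n] - off * cos(perp); st$y[n] <- st$y[n] - off * sin(perp)
  st$theta[n] <- st$theta[i] + pi / 2
  st$theta[i] <- st$theta[i] - pi / 2
  st$static_time[c(i, n)] <- 0
  st$split_ok_at[c(i, n)] <- t + cfg$split_refractory
  st
}

#' Simulate one droplet experiment
#'
#' Injects `cfg$n_droplets` identical droplets near the inlet at the bottom
#' of the dish, advances the agent model for `duration * fps` steps and
#' records every agent's position and state per frame, together with the
#' ground-truth count of droplets moving within the trailing
#' `static_window`: alive droplets displaced by at least `static_dist` over
#' that window (droplets younger than the window count as moving) -- the
#' quantity the vision pipeline's short-memory background model estimates.
#'
#' @param g a [genome()].
#' @param arena an [arena()].
#' @param cfg a [sim_config()].
#' @param seed integer seed; the full trajectory is reproducible from it.
#' @return a `droplet_sim` object: list with `frames` (per-frame matrices of
#'   id, x, y, radius, state, static_time), `counts` (ground-truth moving
#'   count per frame), `traits`, `genome`, `arena`, `cfg`, `seed`.
#' @export
simulate_experiment <- function(g, arena, cfg = sim_config(), seed = 1L) {
  g <- as_genome(g)
  traits <- genome_to_traits(g, cfg$trait_params)
  with_seed(seed, {
    st <- new_agents(cfg$n_droplets, cfg, arena)
    frames <- vector("list", cfg$n_frames)
    counts <- integer(cfg$n_frames)
    win <- max(1L, as.integer(round(cfg$static_window * cfg$fps)))
    for (f in seq_len(cfg$n_frames)) {
      st <- step_droplets(st, arena, traits, cfg$dt, cfg, t = (f - 1) * cfg$dt)
      alive <- st$state != ST_DISSOLVED
      frames[[f]] <- cbind(id = seq_along(st$x), x = st$x, y = st$y,
                           radius = st$radius, state = st$state,
                           static_time = st$static_time)[alive, , drop = FALSE]
      cur <- frames[[f]]
      if (f <= win) counts[f] <- nrow(cur)
      else {
        ref <- frames[[f - win]]
        m <- match(cur[, "id"], ref[, "id"])
        disp <- sqrt((cur[, "x"] - ref[m, "x"])^2 +
                       (cur[, "y"] - ref[m, "y"])^2)
        counts[f] <- sum(is.na(m) | disp >= cfg$static_dist)
      }
    }
    structure(list(frames = frames, counts = counts, traits = traits,
                   genome = g, arena = arena, cfg = cfg, seed = seed),
              class = "droplet_sim")
  })
}

#' @export
print.droplet_sim <- function(x, ...) {
  cat(sprintf("<droplet_sim> %d frames in arena '%s'; final moving count %d\n",
              length(x$frames), x$arena$label, x$counts[length(x$counts)]))
  invisible(x)
}

# fixed rendering intensities (8-bit grayscale)
BG_OUTSIDE <- 30; BG_ARENA <- 200; BG_PILLAR <- 90; FG_DROPLET <- 235

#' Render the static arena background
#'
#' @param arena an [arena()].
#' @param cfg a [sim_config()] (frame size and scale).
#' @return `height x width` numeric matrix of 8-bit intensities.
#' @export
render_background <- function(arena, cfg = sim_config()) {
  h <- cfg$height; w <- cfg$width; p <- cfg$px_per_mm
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ys <- (cy - seq_len(h)) / p              # mm, image row -> y (up positive)
  xs <- (seq_len(w) - cx) / p
  bg <- matrix(BG_OUTSIDE, h, w)
  inside <- outer(ys^2, xs^2, "+") <= arena$radius^2
  bg[inside] <- BG_ARENA
  if (nrow(arena$pillars)) {
    rows <- cy - arena$pillars$y * p
    cols <- cx + arena$pillars$x * p
    bg <- .draw_discs_cpp(bg, rows, cols, arena$pillars$diameter / 2 * p,
                          BG_PILLAR)
    # pillars clipped to the dish
    bg[!inside] <- BG_OUTSIDE
  }
  bg
}

#' Render one video frame
#'
#' Draws the non-dissolved droplets as filled discs of fixed intensity over
#' the static background; optional Gaussian sensor noise.
#'
#' @param agents per-frame agent matrix (as in the `frames` field of
#'   [simulate_experiment()] output).
#' @param arena an [arena()].
#' @param cfg a [sim_config()].
#' @param bg precomputed [render_background()] matrix (recomputed if NULL).
#' @param noise_sd sensor noise standard deviation (0 = off).
#' @return `height x width` numeric matrix.
#' @export
render_frame <- function(agents, arena, cfg = sim_config(), bg = NULL,
                         noise_sd = 0) {
  if (is.null(bg)) bg <- render_background(arena, cfg)
  p <- cfg$px_per_mm
  cy <- (cfg$height + 1) / 2; cx <- (cfg$width + 1) / 2
  if (nrow(agents)) {
    img <- .draw_discs_cpp(bg, cy - agents[, "y"] * p, cx + agents[, "x"] * p,
                           agents[, "radius"] * p, FG_DROPLET)
  } else img <- bg
  if (noise_sd > 0)
    img <- pmin(255, pmax(0, img + rnorm(length(img), 0, noise_sd)))
  img
}

#' Frame stream of a simulated experiment
#'
#' Returns a closure `function(i)` yielding rendered frame `i`, with the
#' frame count in attribute `n_frames` — the lazy video interface consumed by
#' [fitness_from_video()], avoiding materialising 1800 full frames at once.
#'
#' @param sim a `droplet_sim`.
#' @param noise_sd sensor noise sd passed to [render_frame()].
#' @return a frame-generating function.
#' @export
frame_stream <- function(sim, noise_sd = 0) {
  bg <- render_background(sim$arena, sim$cfg)
  f <- function(i) render_frame(sim$frames[[i]], sim$arena, sim$cfg, bg = bg,
                                noise_sd = noise_sd)
  attr(f, "n_frames") <- length(sim$frames)
  f
}
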