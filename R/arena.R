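#' Construct an arena
#'
#' An arena is the circular experimental dish, viewed top-down, plus a set of
#' cylindrical pillar obstacles described by their centres and diameters (all
#' in millimetres, origin at the dish centre).
#'
#' @param radius dish radius in mm.
#' @param pillars data frame with columns `x`, `y`, `diameter` (mm); may have
#'   zero rows.
#' @param label arena identifier (`"empty"`, `"pillars"`, `"lsystem:<seed>"`, ...).
#' @return an `arena` object.
#' @export
arena <- function(radius, pillars = empty_pillars(), label = "arena") {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be positive")
  pillars <- as.data.frame(pillars)
  stopifnot(all(c("x", "y", "diameter") %in% names(pillars)))
  if (nrow(pillars)) {
    if (any(pillars$diameter <= 0)) stop("pillar diameters must be positive")
    if (any(sqrt(pillars$x^2 + pillars$y^2) > radius))
      stop("pillar centres must lie within the boundary")
  }
  structure(list(radius = radius, pillars = pillars, label = label),
            class = "arena")
}

empty_pillars <- function()
  data.frame(x = numeric(0), y = numeric(0), diameter = numeric(0))

#' @export
print.arena <- function(x, ...) {
  cat(sprintf("<arena '%s'> radius %.1f mm, %d pillars\n",
              x$label, x$radius, nrow(x$pillars)))
  invisible(x)
}

#' Empty circular arena
#'
#' The obstacle-free dish used as the first environment of the evolutionary
#' experiments.
#'
#' @param radius dish radius in mm (default 27.5, so the camera's 275 px
#'   region of interest maps at 10 px/mm).
#' @return an `arena` with no pillars.
#' @export
make_empty_arena <- function(radius = 27.5) {
  arena(radius, label = "empty")
}

#' Square-grid pillar arena
#'
#' Pillars of the given diameter placed on a square grid centred on the dish,
#' keeping only pillars that fit entirely inside the boundary; each kept
#' pillar has grid neighbours in the four cardinal directions where the
#' boundary allows.
#'
#' @param radius dish radius, mm.
#' @param spacing centre-to-centre grid spacing, mm (default 3).
#' @param diameter pillar diameter, mm (default 2).
#' @return an `arena` labelled `"pillars"`.
#' @export
make_pillar_arena <- function(radius = 27.5, spacing = 3, diameter = 2) {
  if (spacing <= 0) stop("spacing must be positive")
  if (spacing <= diameter)
    warning("pillar spacing does not exceed the diameter: pillars touch")
  half <- floor(radius / spacing)
  coord <- seq(-half, half) * spacing
  grid <- expand.grid(x = coord, y = coord)
  keep <- sqrt(grid$x^2 + grid$y^2) + diameter / 2 <= radius
  arena(radius,
        data.frame(x = grid$x[keep], y = grid$y[keep], diameter = diameter),
        label = "pillars")
}

#' Specify a stochastic L-system
#'
#' A Lindenmayer system: an axiom string and per-symbol stochastic rewrite
#' rules, expanded in parallel for a number of iterations and interpreted by
#' turtle graphics to drop pillar obstacles (`F` = step forward and place a
#' pillar, `+`/`-` = turn, `[`/`]` = push/pop the turtle state).
#'
#' @param axiom starting symbol string.
#' @param rules named list; each element is a list of alternatives
#'   `list(p = probability, out = expansion string)` whose probabilities sum
#'   to 1. Symbols without rules are copied unchanged.
#' @param iterations number of parallel rewriting rounds.
#' @param step_length turtle step in mm.
#' @param turn_angle turtle turn in degrees.
#' @param seed integer seed driving the stochastic rule choices.
#' @return an `lsystem_spec`.
#' @export
lsystem_spec <- function(axiom = "F",
                         rules = list(F = list(list(p = 0.5, out = "F[+F]F"),
                                               list(p = 0.5, out = "F[-F]"))),
                         iterations = 4, step_length = 3, turn_angle = 25,
                         seed = 1L) {
  for (sym in names(rules)) {
    p <- vapply(rules[[sym]], function(r) r$p, numeric(1))
    if (abs(sum(p) - 1) > 1e-9)
      stop("rule probabilities for '", sym, "' must sum to 1")
  }
  structure(list(axiom = axiom, rules = rules, iterations = iterations,
                 step_length = step_length, turn_angle = turn_angle,
                 seed = as.integer(seed)),
            class = "lsystem_spec")
}

#' Expand an L-system to its symbol string
#'
#' Rewrites the axiom in parallel for `spec$iterations` rounds; stochastic
#' rule alternatives are chosen with the spec's seed, so the same spec always
#' yields the same string.
#'
#' @param spec an [lsystem_spec()].
#' @param max_symbols growth cap; expansion beyond it is an error.
#' @return the expanded symbol string.
#' @export
expand_lsystem <- function(spec, max_symbols = 1e5) {
  stopifnot(inherits(spec, "lsystem_spec"))
  with_seed(spec$seed, {
    s <- strsplit(spec$axiom, "")[[1]]
    for (it in seq_len(spec$iterations)) {
      out <- lapply(s, function(sym) {
        alts <- spec$rules[[sym]]
        if (is.null(alts)) return(sym)
        p <- vapply(alts, function(r) r$p, numeric(1))
        pick <- if (length(alts) == 1L) 1L else sample.int(length(alts), 1L, prob = p)
        strsplit(alts[[pick]]$out, "")[[1]]
      })
      s <- unlist(out)
      if (length(s) > max_symbols)
        stop("L-system expansion exceeded ", max_symbols, " symbols")
    }
    paste(s, collapse = "")
  })
}

#' Interpret an L-system string as a pillar arena
#'
#' Walks a turtle over the expanded string starting at the dish centre,
#' heading up. Each `F` advances one step and drops a pillar at the new
#' position; `+`/`-` turn by the spec's angle; `[`/`]` push/pop the turtle
#' state. Pillars that would cross the boundary or overlap an already placed
#' pillar are discarded (physical pillars cannot interpenetrate).
#'
#' @param s symbol string (normally from [expand_lsystem()]).
#' @param spec the [lsystem_spec()] providing step length and turn angle.
#' @param arena_radius dish radius, mm.
#' @param diameter pillar diameter, mm.
#' @return an `arena` labelled `"lsystem:<seed>"`.
#' @export
interpret_lsystem <- function(s, spec, arena_radius = 27.5, diameter = 2) {
  syms <- strsplit(s, "")[[1]]
  ang <- spec$turn_angle * pi / 180
  pos <- c(0, 0); heading <- pi / 2
  stack <- list()
  px <- numeric(0); py <- numeric(0)
  for (sym in syms) {
    if (sym == "F") {
      pos <- pos + spec$step_length * c(cos(heading), sin(heading))
      inside <- sqrt(sum(pos^2)) + diameter / 2 <= arena_radius
      clear <- !length(px) ||
        all(sqrt((px - pos[1])^2 + (py - pos[2])^2) >= diameter)
      if (inside && clear) { px <- c(px, pos[1]); py <- c(py, pos[2]) }
    } else if (sym == "+") heading <- heading + ang
    else if (sym == "-") heading <- heading - ang
    else if (sym == "[") stack[[length(stack) + 1L]] <- c(pos, heading)
    else if (sym == "]") {
      if (!length(stack)) stop("unbalanced ']' in L-system string")
      st <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      pos <- st[1:2]; heading <- st[3]
    }
  }
  if (length(stack)) stop("unbalanced '[' in L-system string")
  arena(arena_radius,
        data.frame(x = px, y = py, diameter = diameter),
        label = paste0("lsystem:", spec$seed))
}

#' Procedurally generated "caves" arena
#'
#' Convenience wrapper: expand and interpret a stochastic L-system inside the
#' dish. The default grammar with `seed = 7` is the repository's canonical
#' cave-like arena.
#'
#' @inheritParams interpret_lsystem
#' @param seed seed for the stochastic grammar.
#' @param spec optional [lsystem_spec()]; default grammar if omitted.
#' @return an `arena`.
#' @export
make_lsystem_arena <- function(radius = 27.5, seed = 7L, spec = NULL,
                               diameter = 2) {
  if (is.null(spec)) spec <- lsystem_spec(seed = seed)
  else spec$seed <- as.integer(seed)
  interpret_lsystem(expand_lsystem(spec), spec, arena_radius = radius,
                    diameter = diameter)
}

#' Rasterise an arena to an occupancy grid
#'
#' @param a an `arena`.
#' @param px_per_mm raster resolution.
#' @return list with logical matrices `occupied` (pillar interiors) and
#'   `inside` (within the circular boundary), plus the resolution and the
#'   pixel coordinates of the dish centre. Matrices are row = image y,
#'   col = image x.
#' @export
rasterize <- function(a, px_per_mm) {
  stopifnot(inherits(a, "arena"), px_per_mm > 0)
  n <- ceiling(2 * a$radius * px_per_mm)
  cx <- (n + 1) / 2
  xs <- (seq_len(n) - cx) / px_per_mm       # mm coordinates of pixel centres
  inside <- outer(xs^2, xs^2, "+") <= a$radius^2
  occupied <- matrix(FALSE, n, n)
  for (i in seq_len(nrow(a$pillars))) {
    p <- a$pillars[i, ]
    occupied <- occupied |
      outer((xs - p$y)^2, (xs - p$x)^2, "+") <= (p$diameter / 2)^2
  }
  list(occupied = occupied & inside, inside = inside,
       px_per_mm = px_per_mm, center_px = c(cx, cx))
}

#' Read/write arenas as JSON
#'
#' @param a an `arena`.
#' @param path file path.
#' @return `arena_from_json` returns the `arena`; `arena_to_json` its path,
#'   invisibly.
#' @export
arena_to_json <- function(a, path) {
  stopifnot(inherits(a, "arena"))
  jsonlite::write_json(list(radius = a$radius, label = a$label,
                            pillars = a$pillars),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname arena_to_json
#' @export
arena_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pil <- if (length(obj$pillars)) as.data.frame(obj$pillars) else empty_pillars()
  arena(obj$radius, pil, obj$label)
}
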