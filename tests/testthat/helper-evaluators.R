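# deterministic stub evaluators and small configs shared across tests

stub_evaluator <- function(value = 3) {
  function(g, arena, seed) value
}

# deterministic function of the genome only: fitness peaks at `target`
unimodal_evaluator <- function(target = genome(0.1, 0.1, 0.2, 0.6), scale = 10) {
  tg <- unclass(target)
  function(g, arena, seed) {
    d <- sqrt(sum((unclass(as_genome(g)) - tg)^2))
    scale * exp(-3 * d)
  }
}

# reduced-size simulation config used by simulator-backed tests
small_sim_config <- function(...) {
  sim_config(duration = 15, fps = 10, px_per_mm = 4, width = 240, height = 240,
             ...)
}

make_individuals <- function(genomes, fitnesses, repeats = 1) {
  mapply(function(g, f) individual(g, rep(f, repeats)),
         genomes, fitnesses, SIMPLIFY = FALSE)
}
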