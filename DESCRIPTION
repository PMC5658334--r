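Package: dropevo
Title: Artificial Evolution of Self-Propelled Oil Droplets in Programmable Arenas
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An in-silico droplet-protocell evolution platform: a genetic
    algorithm over 4-oil formulation genomes whose fitness is the number of
    droplets still moving at the end of a one-minute video, measured by a
    mixture-of-Gaussians background-subtraction vision pipeline. Includes a
    phenomenological agent-based droplet simulator with pillar-obstacle
    arenas (grid and stochastic L-system "caves"), the evenly spaced lattice
    search over the formulation simplex, RBF-kernel fitness-landscape
    regression (grid-searched SVR and kernel ridge) with ternary prediction
    grids, and population statistics (fitness-weighted genomes, one-way
    ANOVA, genome heat-map encoding, cross-environment testing).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
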