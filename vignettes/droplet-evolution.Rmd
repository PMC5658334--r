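---
title: "Evolving self-propelled droplets in silico: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving self-propelled droplets in silico: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropevo)
```

## The system

`dropevo` is a software re-creation of an artificial-evolution platform for
protocell models: oil-in-water droplets whose recipe — the volume fractions
of 1-octanol, diethyl phthalate (DEP), octanoic acid and 1-pentanol, a point
on the 4-component mixture simplex — determines how they move, divide and
survive in a circular dish that can be furnished with cylindrical pillar
obstacles. A camera watches the dish; a vision pipeline segments moving
droplets from the background; the number of droplets still detected at the
final frame of a one-minute video is the fitness of the recipe; and a
genetic algorithm (GA) breeds recipes against that fitness. Because the
physical device is replaced here by a simulator, every component — genome
operators, arenas, droplet dynamics, rendering, detection, evolution,
lattice search, landscape regression, population statistics — is executable
and testable on a desk.

Two components deserve a clear epistemic label up front:

* **The vision pipeline, GA, lattice search, landscape regression and
  statistics are faithful implementations** of well-defined published
  procedures (mixture-of-Gaussians background subtraction with a short
  memory, roulette selection without replacement, one-point crossover,
  Gaussian mutation, 10-fold cross-validated RBF-SVR grid search, and so
  on).
* **The droplet simulator is a phenomenological stand-in.** No quantitative
  physical model of the droplet system exists; the simulator's job is to
  reproduce the *qualitative* behavioural repertoire (self-propulsion,
  division, hooking onto pillars, trapping, dissolution) with a smooth,
  genome-conditioned parameterisation, so that the surrounding machinery can
  be exercised end to end. Conclusions about real droplet chemistry cannot
  be read off the simulator.

## The genome and its operators

A genome is four non-negative oil fractions summing to 1 (enforced to
1e-9). The GA configuration mirrors the platform's printed constants: 10
generations of 20 individuals, each individual evaluated 5 times with the
mean as its fitness, 10 parents selected by fitness-proportionate roulette
in which a parent can appear only once, and 10 offspring built by one-point
crossover of parent pairs (each parent used exactly twice) followed by
additive Gaussian mutation with mean 0 and variance 0.1, the result clamped
at zero and renormalised.

Choices the source material left open, decided here once:

* **Initial population**: uniform on the simplex (sorted-uniform spacings,
  i.e. a symmetric Dirichlet(1,1,1,1)); "random recipes" is otherwise
  underdetermined and the flat measure is the natural reference.
* **Crossover cut points**: interior cuts {1,2,3} only; cutting at the ends
  would clone a parent. If complementary sparse parents make the child
  identically zero at the drawn cut (for example two different pure oils),
  the other cuts are tried, and parent *a* is returned when every cut is
  degenerate.
* **Mutation clamping**: noise can push a fraction negative; we clamp to 0
  before renormalising and resample in the (measure-zero) all-zero case.
* **Roulette without replacement** is implemented as sequential renormalised
  draws — the simplest scheme consistent with "a parent appears once". When
  every remaining candidate has zero fitness the draw falls back to uniform.
* **Parents are re-evaluated** in the generation they survive into rather
  than carrying cached fitness: the physical platform re-ran every
  individual, and with a stochastic evaluator the two conventions genuinely
  differ.
* **Quartile statistics** follow the platform's convention: for 20
  individuals the top and bottom quartile curves are the 5th and 15th
  individuals by descending mean fitness, ties broken by insertion order.

All randomness descends from one run seed through a splittable scheme
(run → generation → individual → repeat), every experiment seed is logged,
and reruns are byte-identical.

## Arenas

The dish is a circle of radius 27.5 mm — the dish size is not printed
anywhere, so we fix it such that the camera's 275 px region of interest maps
the dish at 10 px/mm; both numbers are configuration values. Three
environments:

* **empty** — no obstacles;
* **pillars** — 2 mm pillars on a 3 mm square grid (1 mm surface gap),
  keeping every pillar that fits inside the boundary;
* **caves** — pillars dropped by a turtle walking a stochastic L-system
  string. The published work shows outcomes but not the grammar, so the
  package default (axiom `F`; `F → F[+F]F` with probability 0.5, `F → F[-F]`
  otherwise; 4 iterations; 3 mm steps; 25° turns) is this package's own
  documented choice, with `seed = 7` frozen as the canonical caves arena.
  Pillars that would cross the boundary or overlap an earlier pillar are
  discarded, since physical pillars cannot interpenetrate.

## The droplet simulator

Each droplet is an agent with position, heading, volume (radius via a
spherical-cap lens coefficient, `r = 0.7 V^{1/3}` mm per µl^⅓) and a state
in {moving, hooked, trapped, dissolved}. Five 10 µl droplets are injected
near the inlet at the bottom of the dish, fanned on a small arc so they
start in contact but not overlapping, and the model is stepped at the video
frame rate for the experiment duration (default 60 s at 30 fps, 1800
frames).

The dynamics per step:

* **Self-propulsion** — active-Brownian motion: constant speed equal to the
  genome's motility with rotational diffusion of the heading
  (0.6 rad²/s) plus velocity noise. The noise amplitude scales with
  motility: propulsion fluctuations vanish for a stalled droplet, which sits
  pinned by its meniscus. This matters for the vision pipeline — a truly
  static droplet must be absorbable into the background at any rendering
  resolution.
* **Collisions** — specular reflection at the dish wall and at pillar
  surfaces; soft-disc droplet–droplet repulsion with a bounded relaxation
  speed (resting contacts must not jitter frame to frame), and no
  coalescence, as the surfactant prevents it in the real system.
* **Squeezing** — droplets are deformable: the effective collision radius
  against pillars is `squeeze_factor = 0.35` of the optical radius,
  otherwise a 10 µl droplet (≈3 mm across) could never pass the 1 mm gaps
  of the pillar grid that the real, deformable droplets negotiate.
* **Division** — volume-halving splits with tangential daughter placement:
  a spontaneous hazard (the genome's division rate, in 1/s) plus a boosted
  chance on each fresh pillar impact, with a 1.5 s refractory period;
  splits stop below 1.25 µl, bounding the population at 8× the injection
  count.
* **Hooking and trapping** — within 1 mm of a pillar surface a droplet may
  hook with probability proportional to its attraction; stable recipes
  unhook after an exponential holding time (mean `4(2 − stability)` s),
  recipes below 0.5 stability are trapped permanently, and hooked/trapped
  droplets dissolve at the genome's decay rate.

**The genome-to-trait map** is smooth (Lipschitz), deterministic and fully
coefficient-parameterised; directions follow the chemistry described for
the real system: pentanol and octanol (soluble, Marangoni-active) drive
motility, DEP contributes none; octanoic acid and overall motility drive
division; pentanol excess beyond 40% erodes stability; DEP and octanoic
acid increase pillar affinity, on top of a baseline affinity every recipe
has. Motility passes through a sharp onset sigmoid centred at 1 mm/s
(width 0.03 mm/s): weak Marangoni propulsion stalls rather than creeping.
The sharpness is not cosmetic — steady sub-millimetre-per-second creep is
exactly the regime a short-memory background subtractor half-absorbs into
flickering fragments, and the onset keeps recipes out of that ambiguous
band, which real droplets (that either run or stall) do not occupy either.

The simulator also records its own **ground truth**: per frame, the number
of live droplets displaced by at least `static_dist = 1.5` mm over the
trailing 3 s window (droplets younger than the window count as moving).
This is the quantity the vision pipeline estimates, and the two are
compared in the test suite.

Every dynamics coefficient lives in `sim_config()` /
`trait_map_params()` with the defaults above. The defaults were chosen so
that the platform's qualitative findings hold in simulation: fitness rises
over generations, an empty→pillars arena swap drops population fitness and
contracts genome diversity, and populations evolved in the empty arena
underperform when moved to obstacle arenas. These are the study conditions
of the package, not tunables per run.

## Rendering and the vision pipeline

Frames are 800 × 600 8-bit grayscale at 10 px/mm: dish interior at
intensity 200, pillars 90, outside 30, droplets drawn as filled discs at
235, optional Gaussian sensor noise (off by default — determinism of the
rendered video given a seed is part of the package contract). Videos are
streamed lazily (`frame_stream()`), never materialised whole.

Detection follows the published pipeline: a circular region of interest of
275 px; per-pixel mixture-of-Gaussians background subtraction
(Stauffer–Grimson style, K = 5 components, squared-Mahalanobis match
threshold 2.5², learning rate 1/history with a 90-frame history, background
set = components whose cumulative weight reaches 0.4); 8-connected
components of the foreground mask with a 20 px² minimum area; and the
fitness of a video is the number of droplets detected in its final frame
(frame 1800 at the default geometry). The original used an OpenCV MoG with
library defaults, which are version-dependent; our hyperparameters are
calibrated to the stated behaviour — an object static for roughly 3 s is
absorbed into the background (measured latency 2.6 s, tested to lie in
[2 s, 5 s]) — not to bit-compatibility.

One departure from a bare find-contours step: detections whose centroids
lie within 0.6 injected-droplet diameters are merged
(`merge_detections()`). A droplet moving near the absorption boundary can
surface as two crescent fragments (leading edge still novel, interior
already absorbed); merging restores the droplet-level count. The residual
failure modes are documented honestly: recipes driven exactly at the
propulsion onset can still fragment, and two droplets in optical contact
are one blob for any connected-component counter. Over random recipes the
final-frame count agrees with the simulator's ground truth within ±1
droplet for the large majority of recipes and exactly on well-separated
synthetic videos; the test suite asserts precisely these statements rather
than a perfection the method does not have.

## Lattice search, landscape models, statistics

The lattice search enumerates formulations at 10% granularity: all
compositions over each pair, triple and quadruple of oils with every member
strictly positive — 54 + 144 + 84 = 282 multi-oil formulations, built in
integer tenths and divided once so the simplex constraint is exact — plus
the four single-oil recipes labelled separately (the published totals
exclude them). One arena × 5 repeats is 1410 experiments.

Fitness landscapes are kernel regressions of fitness on the four fractions
(used directly, unstandardised — they are already bounded; each of the 5
repeats enters as its own point). The SVR route grid-searches
C ∈ {0.01, 0.1, 1, 10, 100} (the printed grid) × γ ∈ {0.01, 0.1, 1, 10,
100} (the γ grid is not printed; ours brackets the reported best values 10
and 100) under seeded 10-fold cross-validated mean squared error, with ties
broken toward smaller C then smaller γ, and refits on all data. We read the
ambiguous phrase about error "on the training set" as CV MSE, consistent
with the stated use of cross-validation. The kernel-ridge route is the
closed-form fit at α = 10, γ = 100 — the variant for time-resolved
landscape sequences, where a single shared kernel keeps frames comparable.
Degenerate folds (constant targets) fall back to predicting the training
mean instead of failing. `ternary_grid()` evaluates a fitted model on the
barycentric grid of three oils with the fourth at zero, the data behind a
ternary heat-map panel; `plot()` renders it.

Population statistics: the fitness-weighted genome (weighted mean ± weighted
standard deviation of each component over a final generation — the weighting
population is switchable, final generation by default); classical one-way
ANOVA (`F = t²` for two groups, exact against long-hand sums of squares);
the heat-map encoding of an average genome (each component rounded to one
decimal, slots 0–9 mapped to letters A–J in row order pentanol, octanoic,
DEP, octanol — the original letter convention is not reconstructible from
the published figure, so this one is ours and is stated); and the
cross-environment matrix re-evaluating each arena's final population in
every arena.

## Problem sizes and numerical choices

The package defaults reproduce the platform's experiment sizes (20 × 10 × 5
= 1000 experiments per GA run; 1410 lattice videos per arena; 1800-frame
videos at 800 × 600). The test suite and the acceptance script exercise the
full-size vision pipeline on scripted synthetic videos, and run the
simulator-backed evolutionary properties at reduced sizes chosen as the
smallest that still show the effects clearly: 20 s videos at 10 fps for
simulator checks, the platform's population of 20 with 3 repeats and a
5 + 5 generation schedule for the environment-swap property (the
genome-diversity contraction is measured as the post-swap minimum falling
below the pre-swap level — filtering acts at the swap, and mutation
reinjects variance in later generations), and the simulator's own
ground-truth count (which the vision pipeline is separately shown to track)
as the evaluator in multi-run studies. The vignette states these as the
package's chosen study sizes; all of them scale up by changing the
configuration objects only.

Numerical details worth knowing: genome validity is enforced at 1e-9 and
lattice genomes are exact by construction; the kernel-ridge solve jitters
the Gram matrix by 1e-8 on singularity; CV fold assignment is a seeded
permutation, so the selected hyperparameters are invariant to row order;
ranking ties anywhere use insertion order; and all derived seeds stay below
2³¹.

## Known limitations

* The simulator is phenomenological: no Marangoni flow fields, surfactant
  transport, pH chemistry or 3D effects; its coefficients are
  order-of-magnitude choices, not measurements. Passing tests show the
  *platform* behaves like the original as a system, not that the dynamics
  model predicts real droplets.
* Counting by connected components cannot distinguish touching droplets,
  and recipes at the propulsion onset can fragment; both failure modes are
  quantified in the tests.
* Droplet identity is not tracked across frames (the fitness definition
  never needs it).
* The published cross-validated MSE values of the physical landscape models
  (6.83 / 21.30 / 11.50) depend on the physical data and are out of reach
  by construction; they are documented as non-targets.
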