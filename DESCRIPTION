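Package: epivertex
Title: Stochastic Epithelial Vertex-Model Simulation with Explicit Friction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the growth of a planar epithelium with a vertex model in
    which every tri-cellular junction follows overdamped dynamics with an
    explicit friction coefficient. Cells progress through a stochastic cell
    cycle (a shifted-exponential intrinsic cycle length driving a piecewise
    target-area schedule), divide when they satisfy age and critical-area
    conditions, and rearrange through T1 edge swaps and T2 extrusions.
    Companion age-structured growth theory (division hazard, stationary age
    density, Euler-Lotka solvers, and a newborn-fraction growth-rate
    estimator) and a non-spatial branching-process sampler allow the spatial
    simulations to be compared against intrinsic, deterministic and
    age-structure growth predictions, in particular to quantify how the
    friction coefficient reshapes morphology, cell-cycle duration, tissue
    growth rate and topological-transition counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
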