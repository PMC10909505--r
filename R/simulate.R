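#' Full simulation configuration
#'
#' Bundles mechanical, cell-cycle and topological parameters with the run
#' protocol (initial lattice size, stop condition, snapshot cadence, RNG
#' seed).  One seed governs every stochastic draw of a run (initial cycle
#' lengths, division-plane angles, daughter cycle lengths), making runs
#' bit-reproducible.
#'
#' @param n0 initial number of cells in the hexagonal lattice.
#' @param initial_area initial cell area (sets the hexagon side).
#' @param mech a [mech_params()].
#' @param cycle a [cycle_params()].
#' @param topo a [topo_params()].
#' @param t_max stop time. The standard protocol runs `t = 3200`, about ten
#'   mean cycle durations.
#' @param n_max stop cell count (use `Inf` to stop on time only).
#' @param seed RNG seed (integer) or `NULL` to use the current RNG state.
#' @param snapshot_dt metrics cadence; default `Tc / 10`.
#' @param division_rule `"random"` (uniform division-plane angle) or
#'   `"short_axis"`.
#' @param divisions_enabled `FALSE` freezes the cell cycle (mechanics-only
#'   runs with static targets).
#' @param max_steps hard cap on integration steps.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n0 = 100, initial_area = 1,
                              mech = mech_params(),
                              cycle = cycle_params(),
                              topo = topo_params(),
                              t_max = 3200, n_max = Inf, seed = NULL,
                              snapshot_dt = cycle$Tc / 10,
                              division_rule = c("random", "short_axis"),
                              divisions_enabled = TRUE,
                              max_steps = 5e8) {
  division_rule <- match.arg(division_rule)
  stopifnot(n0 >= 1, initial_area > 0, t_max > 0 || is.finite(n_max),
            snapshot_dt > 0)
  if (!is.finite(t_max) && !is.finite(n_max))
    stop("a stop condition is required: finite `t_max` or `n_max`")
  structure(list(n0 = as.integer(n0), initial_area = initial_area,
                 mech = mech, cycle = cycle, topo = topo,
                 t_max = t_max, n_max = n_max, seed = seed,
                 snapshot_dt = snapshot_dt, division_rule = division_rule,
                 divisions_enabled = divisions_enabled,
                 max_steps = max_steps),
            class = "simulation_config")
}

#' Run a vertex-model tissue simulation
#'
#' The main loop advances the tissue one forward-Euler step at a time:
#' compute forces from the current target areas, move the vertices by
#' `(dt / gamma) * F`, resolve topological transitions (T1 then T2), then
#' check every cell's division conditions, splitting the ready ones.
#' Metrics are recorded every `snapshot_dt` time units.
#'
#' @param config a [simulation_config()].
#' @param mesh optional starting [tissue_mesh()]; by default a fresh
#'   hexagonal lattice of `n0` cells of area `initial_area`, with birth time
#'   0 and independent intrinsic cycle draws.
#' @return an object of class `vm_sim`: list with `mesh` (final state),
#'   `metrics` (tibble: time, n_cells, mean/sd area, mean shape index,
#'   cumulative division/T1/T2 counts), `events` (tibble event log) and
#'   `config`.
#' @export
run_simulation <- function(config = simulation_config(), mesh = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(mesh)) {
    side <- sqrt(config$initial_area * 2 / (3 * sqrt(3)))
    mesh <- build_hexagonal_lattice(config$n0, side)
    mesh$tc <- sample_tc(length(mesh$cells), config$cycle)
  }
  params <- list(
    K = config$mech$K, Lambda = config$mech$Lambda, Gamma = config$mech$Gamma,
    gamma = config$mech$gamma, dt = config$mech$dt,
    Tc = config$cycle$Tc, epsilon = config$cycle$epsilon,
    A_f = config$cycle$A_f, A_c = config$cycle$A_c,
    with_area_gate = config$cycle$with_area_gate,
    divisions_enabled = config$divisions_enabled,
    division_rule = if (config$division_rule == "short_axis") 1L else 0L,
    l_t1 = config$topo$l_t1, l_new = config$topo$l_new,
    a_t2 = config$topo$a_t2)
  control <- list(t_max = config$t_max, n_max = config$n_max,
                  snapshot_dt = config$snapshot_dt,
                  max_topo_iter = 1000L, max_steps = config$max_steps)
  out <- cpp_run(unclass(mesh), params, control)
  metrics <- tibble::as_tibble(out$metrics)
  metrics <- metrics[!duplicated(metrics$time, fromLast = TRUE), , drop = FALSE]
  res <- list(mesh = structure(out$mesh, class = "tissue_mesh"),
              metrics = metrics,
              events = tibble::as_tibble(out$events),
              step_capped = out$step_capped,
              config = config)
  class(res) <- "vm_sim"
  res
}

#' @export
print.vm_sim <- function(x, ...) {
  m <- x$mesh
  ev <- table(factor(x$events$kind, levels = c("division", "T1", "T2", "peel")))
  cat(sprintf("<vm_sim> %d cells at t = %.4g (gamma = %g)\n",
              length(m$cells), m$time, x$config$mech$gamma))
  cat(sprintf("  events: %d divisions, %d T1, %d T2, %d peel\n",
              ev["division"], ev["T1"], ev["T2"], ev["peel"]))
  invisible(x)
}

#' Bookkeeping identity of a run
#'
#' Checks `N(t) = N0 + divisions - T2 - peel` against the event log.
#'
#' @param sim a `vm_sim`.
#' @return `TRUE` invisibly, or an error describing the mismatch.
#' @export
check_cell_count_identity <- function(sim) {
  ev <- sim$events
  expected <- sim$config$n0 + sum(ev$kind == "division") -
    sum(ev$kind %in% c("T2", "peel"))
  got <- length(sim$mesh$cells)
  if (expected != got)
    stop("cell-count identity violated: expected ", expected, ", mesh has ", got)
  invisible(TRUE)
}

#' Division statistics of a run
#'
#' @param sim a `vm_sim`.
#' @return tibble of division events: `time`, `parent_age`, `parent_area`.
#' @export
division_table <- function(sim) {
  d <- sim$events[sim$events$kind == "division", , drop = FALSE]
  tibble::tibble(time = d$time, parent_age = d$parent_age,
                 parent_area = d$parent_area)
}

#' Growth-rate summary of a simulated tissue
#'
#' Confronts the fitted exponential growth of a run with the three
#' theoretical predictions: the intrinsic Euler--Lotka rate of the
#' parametric cycle distribution, the deterministic rate
#' `ln(2) / <T>_cell` computed from the cycle durations realised in the
#' simulation, and the age-structure rate `N(t,0) / (2 N(t))` read off the
#' final snapshot.
#'
#' @param sim a `vm_sim`.
#' @param t_min snapshots earlier than this are excluded from the
#'   exponential fit; defaults to one mean cycle duration (the initial
#'   synchronisation transient).
#' @param delta newborn window for the age-structure estimator; default 2
#'   percent of `Tc`.
#' @return tibble with columns `method`, `k`, `se`.
#' @export
summarise_growth <- function(sim, t_min = sim$config$cycle$Tc,
                             delta = 0.02 * sim$config$cycle$Tc) {
  cp <- sim$config$cycle
  fit <- fit_growth_rate(sim$metrics, t_min = t_min)
  divs <- division_table(sim)
  kd <- if (nrow(divs) > 0) k_det(mean(divs$parent_age)) else NA_real_
  ages <- sim$mesh$time - sim$mesh$birth_time
  kage <- tryCatch(ksto_from_age_structure(ages, delta),
                   error = function(e) growth_estimate(NA_real_, method = "age_structure"))
  ki <- solve_euler_lotka(cycle_distribution(cp$epsilon, cp$Tc))
  tibble::tibble(
    method = c("fit", "intrinsic_euler_lotka", "deterministic_mean_cycle",
               "age_structure"),
    k = c(fit$estimate, ki, kd, kage$estimate),
    se = c(fit$se, NA_real_, NA_real_, kage$se))
}
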