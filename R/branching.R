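#' Non-spatial branching-process simulation of the intrinsic cell cycle
#'
#' The reference model with no cell--cell interaction: every cell divides
#' exactly when its age reaches its sampled intrinsic cycle length, and each
#' daughter draws a fresh independent length.  This is the process whose
#' growth rate the Euler--Lotka equation predicts, and it serves as the
#' oracle against which both the analytic solvers and the spatial
#' simulations are compared.
#'
#' The implementation is wave-vectorised: all divisions scheduled inside the
#' horizon spawn their daughters in one pass per generation.
#'
#' @param params a [cycle_params()] (only `Tc` and `epsilon` are used).
#' @param t_end simulation horizon.
#' @param n0 initial number of cells (all born at time 0).
#' @param cap population cap to bound memory; exceeding it truncates the run
#'   (with `capped = TRUE`).
#' @param n_grid number of points of the returned `N(t)` trajectory.
#' @return list with
#'   * `trajectory`: tibble `time`, `n_cells`;
#'   * `ages`: cell ages at `t_end` (one entry per alive cell);
#'   * `durations`: all cycle durations completed within the horizon;
#'   * `capped`: logical.
#' @export
branching_process_simulate <- function(params = cycle_params(), t_end, n0,
                                       cap = 2e6, n_grid = 201) {
  stopifnot(n0 >= 1, t_end > 0)
  birth <- rep(0, n0)
  tc <- sample_tc(n0, params)
  all_birth <- birth
  all_div <- birth + tc
  capped <- FALSE

  frontier_div <- all_div
  repeat {
    parents <- frontier_div[frontier_div <= t_end]
    if (!length(parents)) break
    if (length(all_birth) + 2 * length(parents) > cap) {
      capped <- TRUE
      break
    }
    kid_birth <- rep(parents, each = 2)
    kid_tc <- sample_tc(length(kid_birth), params)
    kid_div <- kid_birth + kid_tc
    all_birth <- c(all_birth, kid_birth)
    all_div <- c(all_div, kid_div)
    frontier_div <- kid_div
  }

  divided <- all_div <= t_end
  grid <- seq(0, t_end, length.out = n_grid)
  n_at <- vapply(grid, function(t) sum(all_birth <= t) - sum(all_div <= t),
                 double(1))
  list(
    trajectory = tibble::tibble(time = grid, n_cells = n_at),
    ages = t_end - all_birth[!divided & all_birth <= t_end],
    durations = (all_div - all_birth)[divided],
    capped = capped
  )
}
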