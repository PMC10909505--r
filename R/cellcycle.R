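#' Cell-cycle parameters
#'
#' The intrinsic cycle length of a cell is drawn at birth as
#' \deqn{t_c \sim \varepsilon T_c + \mathrm{Exp}\big((1-\varepsilon)T_c\big),}
#' a deterministic minimum plus an exponential tail, so that
#' \eqn{\langle t_c \rangle = T_c} and the support is \eqn{[\varepsilon T_c, \infty)}.
#' While the cell ages, its target area follows the piecewise schedule
#' \eqn{A^0(t) = 1} for \eqn{t < t_c/2} and \eqn{A^0(t) = 2t/t_c} afterwards,
#' clamped at `A_f` (the maximum target area of a mitotic cell) so the
#' elastic drive stays bounded when division is delayed.  Cytokinesis
#' requires age `>= tc` and, when the area gate is on, current apical area
#' `>= A_c`.
#'
#' @param Tc mean intrinsic cycle duration (time units, > 0). Default 388.
#' @param epsilon deterministic fraction in `[0, 1]`. Default 0.8.
#' @param A_f maximum target area of a mitotic cell. Default 2.
#' @param A_c critical division area; default `0.78 * A_f`.
#' @param with_area_gate logical; `FALSE` removes the critical-area condition
#'   (the `A_c = 0` ablation).
#' @return a list of class `cycle_params`.
#' @export
cycle_params <- function(Tc = 388, epsilon = 0.8, A_f = 2, A_c = 0.78 * A_f,
                         with_area_gate = TRUE) {
  stopifnot(Tc > 0, epsilon >= 0, epsilon <= 1, A_f > 0, A_c >= 0, A_c <= A_f)
  structure(list(Tc = Tc, epsilon = epsilon, A_f = A_f, A_c = A_c,
                 with_area_gate = isTRUE(with_area_gate)),
            class = "cycle_params")
}

#' Sample intrinsic cell-cycle lengths
#'
#' @param n number of draws.
#' @param params a [cycle_params()].
#' @return numeric vector of cycle lengths with mean `Tc` and minimum
#'   `epsilon * Tc`.
#' @export
sample_tc <- function(n, params = cycle_params()) {
  eps <- params$epsilon
  if (eps >= 1) return(rep(params$Tc, n))
  params$Tc * eps + rexp(n, rate = 1 / ((1 - eps) * params$Tc))
}

#' Target-area schedule of a growing cell
#'
#' @param age cell age (>= 0).
#' @param tc the cell's intrinsic cycle length (> 0).
#' @param A_f clamp value (maximum target area of a mitotic cell).
#' @return target area: 1 before `tc / 2`, then `2 * age / tc` clamped at
#'   `A_f`.  Vectorised over `age` and `tc`.
#' @export
target_area <- function(age, tc, A_f = 2) {
  if (any(age < 0)) stop("`age` must be non-negative")
  stopifnot(all(tc > 0))
  ifelse(age < tc / 2, 1, pmin(2 * age / tc, A_f))
}

#' Is a cell ready to divide?
#'
#' True when the cell's age has reached its intrinsic cycle length and --
#' with the area gate on -- its current apical area has reached `A_c`.
#'
#' @param age cell age (time since birth).
#' @param tc the cell's sampled intrinsic cycle length.
#' @param area current apical area from the mesh geometry.
#' @param params a [cycle_params()].
#' @return logical, vectorised.
#' @export
division_ready <- function(age, tc, area, params = cycle_params()) {
  age >= tc & (!params$with_area_gate | area >= params$A_c)
}

#' Divide one cell of a mesh
#'
#' The cell polygon is split by a line through its area centroid.  By
#' default the line direction is uniformly random; `rule = "short_axis"`
#' splits along the minor principal axis (perpendicular to the cell's long
#' axis).  One new vertex is inserted on each of the two crossed edges (and
#' into the neighbouring cells' loops, preserving tri-junctions).  Daughters
#' get fresh ids, `birth_time = now`, independent `tc` draws, and restart
#' the target-area schedule at 1.  If the split fails to produce two simple
#' positive-area polygons the orientation is re-drawn a bounded number of
#' times; after that the division is deferred (`applied = FALSE`).
#'
#' @param mesh a [tissue_mesh()].
#' @param cell_id stable id of the dividing cell (>= 4 vertices).
#' @param params a [cycle_params()] used for the daughters' `tc` draws.
#' @param rule `"random"` or `"short_axis"`.
#' @param angle optional fixed split-line angle (radians), overriding `rule`.
#' @param max_retries bounded retries with a perturbed orientation.
#' @return list with `mesh` (the updated [tissue_mesh()]), `applied`
#'   (logical) and `events` (tibble of division records: time, parent and
#'   daughter ids, parent age and area).
#' @export
divide_cell <- function(mesh, cell_id, params = cycle_params(),
                        rule = c("random", "short_axis"), angle = NULL,
                        max_retries = 8) {
  rule <- match.arg(rule)
  i <- match(cell_id, mesh$cell_id)
  if (is.na(i)) stop("unknown cell_id: ", cell_id)
  if (length(mesh$cells[[i]]) < 4)
    return(list(mesh = mesh, applied = FALSE,
                events = empty_event_log()))
  if (is.null(angle)) {
    angle <- if (rule == "short_axis") short_axis_angle(mesh, i)
             else runif(1, 0, pi)
  }
  tcs <- sample_tc(2, params)
  out <- cpp_divide(unclass(mesh), i, angle, tcs[1], tcs[2],
                    as.integer(max_retries))
  list(mesh = structure(out$mesh, class = "tissue_mesh"),
       applied = out$applied,
       events = tibble::as_tibble(out$events))
}

short_axis_angle <- function(mesh, i) {
  xy <- mesh$vertices[mesh$cells[[i]], , drop = FALSE]
  xy <- sweep(xy, 2, colMeans(xy))
  s <- crossprod(xy)
  0.5 * atan2(2 * s[1, 2], s[1, 1] - s[2, 2]) + pi / 2
}

empty_event_log <- function() {
  tibble::tibble(time = double(), kind = character(),
                 cell1 = integer(), cell2 = integer(), cell3 = integer(),
                 cell4 = integer(), parent_age = double(),
                 parent_area = double())
}
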