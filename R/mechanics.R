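#' Mechanical parameters of the vertex model
#'
#' Constants of the energy functional and of the overdamped dynamics:
#' \deqn{E = \sum_\alpha \left[\frac{K}{2}(A_\alpha - A^0_\alpha)^2 +
#'   \frac{\Gamma}{2} L_\alpha^2\right] + \sum_{\langle ij\rangle} \Lambda\, l_{ij},}
#' \deqn{\gamma \frac{dr_i}{dt} = F_i = -\nabla_i E.}
#' The edge sum visits each unordered edge exactly once (an interior edge
#' shared by two cells is *not* double-counted).  Defaults are the standard
#' parameter set used throughout the package: `K = 1`, `Lambda = 0.05`,
#' `Gamma = 0.02` in simulation units.
#'
#' @param K area elasticity (> 0).
#' @param Lambda edge line tension (may be negative in general models).
#' @param Gamma perimeter contractility.
#' @param gamma friction coefficient (> 0); sets the mechanical relaxation
#'   timescale `gamma / K`.
#' @param dt forward-Euler step; default `0.05 * gamma / K`, a conservative
#'   fraction of the relaxation timescale.
#' @return a list of class `mech_params`.
#' @export
mech_params <- function(K = 1, Lambda = 0.05, Gamma = 0.02, gamma = 1,
                        dt = 0.05 * gamma / K) {
  stopifnot(K > 0, gamma > 0, dt > 0, is.finite(Lambda), is.finite(Gamma))
  structure(list(K = K, Lambda = Lambda, Gamma = Gamma, gamma = gamma, dt = dt),
            class = "mech_params")
}

resolve_targets <- function(mesh, targets) {
  nc <- length(mesh$cells)
  if (length(targets) == 1) targets <- rep(targets, nc)
  if (length(targets) != nc)
    stop("`targets` must supply a target area for every cell (need ", nc, ")")
  as.double(targets)
}

#' Total mechanical energy of a mesh
#'
#' @param mesh a [tissue_mesh()].
#' @param targets per-cell target areas \eqn{A^0_\alpha} (scalar recycled).
#' @param params a [mech_params()].
#' @return scalar energy.
#' @export
total_energy <- function(mesh, targets, params = mech_params()) {
  cpp_energy(unclass(mesh), resolve_targets(mesh, targets),
             params$K, params$Lambda, params$Gamma)
}

#' Analytic vertex forces
#'
#' The exact gradient \eqn{F_i = -\nabla_i E}: the area term uses the
#' shoelace derivative, the contractility term the sum of unit tangents, and
#' the line-tension term the unit edge vectors with each unordered edge
#' contributing once.
#'
#' @inheritParams total_energy
#' @return numeric matrix (vertices x 2) of forces.
#' @export
forces <- function(mesh, targets, params = mech_params()) {
  cpp_forces(unclass(mesh), resolve_targets(mesh, targets),
             params$K, params$Lambda, params$Gamma)
}

#' One forward-Euler step of the overdamped dynamics
#'
#' `r_i <- r_i + (dt / gamma) * F_i`; the mesh time advances by `dt`.
#'
#' @inheritParams total_energy
#' @param force_field optional precomputed force matrix from [forces()];
#'   recomputed when omitted.
#' @return the stepped [tissue_mesh()].
#' @export
step_mesh <- function(mesh, targets, params = mech_params(),
                      force_field = NULL) {
  if (is.null(force_field)) force_field <- forces(mesh, targets, params)
  if (nrow(force_field) != nrow(mesh$vertices))
    stop("force field does not match the mesh")
  mesh$vertices <- mesh$vertices + (params$dt / params$gamma) * force_field
  mesh$time <- mesh$time + params$dt
  mesh
}

#' Relax a mesh to a force balance
#'
#' Iterates [step_mesh()] with static targets until the largest vertex force
#' falls below `tol` or `max_steps` is reached.  Non-convergence is reported
#' through the `converged` attribute, not an error.
#'
#' @inheritParams total_energy
#' @param tol force tolerance (> 0).
#' @param max_steps iteration cap.
#' @return the relaxed [tissue_mesh()] with attributes `converged` (logical)
#'   and `steps` (integer).
#' @export
relax_mesh <- function(mesh, targets, params = mech_params(), tol = 1e-8,
                       max_steps = 100000) {
  stopifnot(tol > 0)
  out <- cpp_relax(unclass(mesh), resolve_targets(mesh, targets),
                   params$K, params$Lambda, params$Gamma,
                   params$gamma, params$dt, tol, as.integer(max_steps))
  m <- structure(out$mesh, class = "tissue_mesh")
  attr(m, "converged") <- out$converged
  attr(m, "steps") <- out$steps
  m
}
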