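#' Topological-transition parameters
#'
#' Thresholds for the moves that keep the tessellation valid while it
#' deforms: a T1 edge swap fires when an interior edge between two
#' tri-junctions shrinks below `l_t1` (the edge is rotated 90 degrees about
#' its midpoint and rescaled to `l_new > l_t1`, exchanging the adjacency of
#' the four incident cells), and a T2 extrusion removes a 3-sided cell whose
#' area falls below `a_t2`, replacing it with a single vertex at its
#' centroid.  Values are in units where the initial cell area is 1.
#'
#' @param l_t1 T1 trigger edge length. Default 0.05.
#' @param l_new post-T1 edge length (> `l_t1`). Default 0.06.
#' @param a_t2 T2 area threshold. Default 0.02.
#' @return a list of class `topo_params`.
#' @export
topo_params <- function(l_t1 = 0.05, l_new = 0.06, a_t2 = 0.02) {
  stopifnot(l_t1 > 0, l_new > l_t1, a_t2 > 0)
  structure(list(l_t1 = l_t1, l_new = l_new, a_t2 = a_t2),
            class = "topo_params")
}

#' Apply one T1 edge swap
#'
#' The edge must be interior (shared by two cells) with both endpoints
#' tri-junctions; otherwise the move is skipped and the reason reported.
#'
#' @param mesh a [tissue_mesh()].
#' @param v1,v2 vertex indices (rows of `mesh$vertices`) of the edge.
#' @param params a [topo_params()] (supplies `l_new`).
#' @return list with `mesh`, `applied` (logical), `reason` (why a skip
#'   happened, `""` otherwise) and `cells` (ids of the four cells whose
#'   adjacency changed: the two that lost the edge, then the two that gained
#'   it).
#' @export
apply_T1 <- function(mesh, v1, v2, params = topo_params()) {
  out <- cpp_t1(unclass(mesh), as.integer(v1), as.integer(v2), params$l_new)
  list(mesh = structure(out$mesh, class = "tissue_mesh"),
       applied = out$applied, reason = out$reason, cells = out$cells)
}

#' Apply one T2 removal
#'
#' A 3-sided interior cell collapses to a single vertex at its centroid and
#' each neighbour loses one side.  A 3-sided cell with a boundary edge is
#' peeled (its loop deleted) instead.  Cells with more than 3 sides are not
#' removed (they must first shrink to a triangle through T1 swaps).
#'
#' @param mesh a [tissue_mesh()].
#' @param cell_id stable id of the cell to remove.
#' @return list with `mesh`, `applied` (logical), `kind` (`"T2"`, `"peel"`
#'   or `NA` when skipped) and `reason`.
#' @export
apply_T2 <- function(mesh, cell_id) {
  i <- match(cell_id, mesh$cell_id)
  if (is.na(i)) stop("unknown cell_id: ", cell_id)
  out <- cpp_t2(unclass(mesh), i)
  list(mesh = structure(out$mesh, class = "tissue_mesh"),
       applied = out$result > 0,
       kind = c(NA_character_, "T2", "peel")[out$result + 1L],
       reason = out$reason)
}

#' Resolve all pending topological transitions
#'
#' Repeatedly applies eligible T1 swaps (shortest edge first, ties broken by
#' the lowest stable vertex id) and then T2 removals (smallest triangle
#' first) until no interior edge is shorter than `l_t1` and no triangle
#' smaller than `a_t2`, or until `max_iter` moves.  Deterministic for a
#' given mesh.
#'
#' @param mesh a [tissue_mesh()].
#' @param params a [topo_params()].
#' @param max_iter cap on the number of moves.
#' @return list with `mesh`, `events` (tibble event log) and `capped`
#'   (logical; `TRUE` when the iteration cap stopped the sweep early, with a
#'   warning).
#' @export
sweep_topology <- function(mesh, params = topo_params(), max_iter = 1000) {
  out <- cpp_sweep(unclass(mesh), params$l_t1, params$l_new, params$a_t2,
                   as.integer(max_iter))
  if (out$capped) warning("topology sweep hit the iteration cap; partial result")
  list(mesh = structure(out$mesh, class = "tissue_mesh"),
       events = tibble::as_tibble(out$events), capped = out$capped)
}
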