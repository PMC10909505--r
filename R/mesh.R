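#' Construct a tissue mesh from vertices and cell loops
#'
#' A `tissue_mesh` is a shared-vertex polygonal tessellation: a matrix of 2D
#' vertex positions plus, for each cell, an ordered loop of vertex indices.
#' Loops are normalised to counter-clockwise orientation at construction.
#' Per-cell cell-cycle state (birth time, sampled intrinsic cycle length
#' `tc`, parent lineage id) is carried alongside the geometry so that a mesh
#' is a complete simulation state.
#'
#' @param vertices numeric matrix with two columns (x, y).
#' @param cells list of integer vectors; each is an ordered loop of row
#'   indices into `vertices`.  Clockwise loops are reversed.
#' @param time simulation time attached to the mesh.
#' @param birth_time,tc,parent_id optional per-cell state vectors (recycled);
#'   defaults: birth at `time`, infinite cycle length (mechanics-only mesh),
#'   no parent.
#' @return an object of class `tissue_mesh`.
#' @export
tissue_mesh <- function(vertices, cells, time = 0,
                        birth_time = time, tc = Inf, parent_id = NA_integer_) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || !is.numeric(vertices))
    stop("`vertices` must be a numeric matrix with columns x, y")
  if (!length(cells)) stop("at least one cell is required")
  cells <- lapply(cells, as.integer)
  nc <- length(cells)
  for (i in seq_len(nc)) {
    L <- cells[[i]]
    if (length(L) < 3) stop("cell loops need at least 3 vertices")
    if (any(L < 1L | L > nrow(vertices)))
      stop("cell loop refers to a vertex index outside `vertices`")
    if (anyDuplicated(L)) stop("cell loop repeats a vertex")
    if (shoelace_area(vertices[L, , drop = FALSE]) < 0) cells[[i]] <- rev(L)
  }
  structure(list(
    vertices = unname(vertices),
    vertex_id = seq_len(nrow(vertices)) - 1L,
    cells = cells,
    cell_id = seq_len(nc) - 1L,
    birth_time = as.double(rep_len(birth_time, nc)),
    tc = as.double(rep_len(tc, nc)),
    parent_id = as.integer(rep_len(parent_id, nc)),
    time = as.double(time),
    next_vertex_id = nrow(vertices),
    next_cell_id = nc
  ), class = "tissue_mesh")
}

shoelace_area <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1)
  0.5 * sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])
}

#' @export
print.tissue_mesh <- function(x, ...) {
  cat(sprintf("<tissue_mesh> %d cells, %d vertices, time = %g\n",
              length(x$cells), nrow(x$vertices), x$time))
  invisible(x)
}

#' Number of cells in a mesh
#' @param mesh a [tissue_mesh()].
#' @return integer cell count.
#' @export
n_cells <- function(mesh) length(mesh$cells)

#' Per-cell cell-cycle state as a tibble
#' @param mesh a [tissue_mesh()].
#' @return tibble with one row per cell: `cell_id`, `birth_time`, `tc`,
#'   `parent_id`, and current `age`.
#' @export
cell_states <- function(mesh) {
  tibble::tibble(
    cell_id = mesh$cell_id,
    birth_time = mesh$birth_time,
    tc = mesh$tc,
    parent_id = mesh$parent_id,
    age = mesh$time - mesh$birth_time
  )
}

#' Build an initial hexagonal lattice
#'
#' Rows of regular hexagons of edge length `side` with shared vertices
#' deduplicated (tolerance `1e-9 * side`); the last row is truncated so the
#' cell count is exactly `n_cells`.  All loops are counter-clockwise.  With
#' `side = sqrt(2 / (3 * sqrt(3)))` (the default) every cell has unit area,
#' matching the usual convention that the initial target area is 1.
#'
#' @param n_cells number of hexagonal cells (>= 1).
#' @param side hexagon edge length (> 0).
#' @param time simulation time stamped on the mesh.
#' @return a [tissue_mesh()].
#' @examples
#' build_hexagonal_lattice(7)
#' @export
build_hexagonal_lattice <- function(n_cells, side = sqrt(2 / (3 * sqrt(3))),
                                    time = 0) {
  if (!is.numeric(n_cells) || length(n_cells) != 1 || n_cells < 1 ||
      n_cells != round(n_cells))
    stop("`n_cells` must be a positive integer")
  if (!is.numeric(side) || length(side) != 1 || side <= 0)
    stop("`side` must be a positive length")
  n_cells <- as.integer(n_cells)

  ncol_ <- ceiling(sqrt(n_cells))
  # pointy-top hexagons; odd rows offset by half a horizontal spacing
  hx <- sqrt(3) * side
  ang <- pi / 6 + pi / 3 * (0:5)     # CCW vertex angles
  vx_off <- side * cos(ang)
  vy_off <- side * sin(ang)

  key_tol <- 1e-9 * side
  vkey <- character(0)
  verts <- matrix(numeric(0), ncol = 2)
  vmap <- new.env(hash = TRUE, parent = emptyenv())
  loops <- vector("list", n_cells)

  cidx <- 0L
  row <- 0L
  while (cidx < n_cells) {
    for (col in seq_len(ncol_)) {
      if (cidx >= n_cells) break
      cx <- (col - 1) * hx + (row %% 2L) * hx / 2
      cy <- row * 1.5 * side
      loop <- integer(6)
      for (k in 1:6) {
        x <- cx + vx_off[k]; y <- cy + vy_off[k]
        key <- paste(round(x / key_tol), round(y / key_tol))
        id <- vmap[[key]]
        if (is.null(id)) {
          verts <- rbind(verts, c(x, y))
          id <- nrow(verts)
          assign(key, id, envir = vmap)
        }
        loop[k] <- id
      }
      cidx <- cidx + 1L
      loops[[cidx]] <- loop
    }
    row <- row + 1L
  }
  tissue_mesh(verts, loops, time = time)
}

#' Geometry of one cell or of every cell
#'
#' Shoelace area, perimeter, neighbour count (loop length) and area-weighted
#' centroid.  Loops must be counter-clockwise; a clockwise loop (negative
#' shoelace area) is treated as a surgery bug and raises an error rather than
#' being silently re-oriented.
#'
#' @param mesh a [tissue_mesh()].
#' @param cell_id optional stable cell id; omit for all cells.
#' @return tibble with columns `cell_id`, `area`, `perimeter`,
#'   `neighbour_count`, `centroid_x`, `centroid_y`, `shape_index`.
#' @export
cell_geometry <- function(mesh, cell_id = NULL) {
  idx <- if (is.null(cell_id)) seq_along(mesh$cells) else {
    i <- match(cell_id, mesh$cell_id)
    if (anyNA(i)) stop("unknown cell_id: ", paste(cell_id[is.na(i)], collapse = ", "))
    i
  }
  rows <- lapply(idx, function(i) {
    xy <- mesh$vertices[mesh$cells[[i]], , drop = FALSE]
    a <- shoelace_area(xy)
    if (a <= 0)
      stop("cell ", mesh$cell_id[i],
           " has a clockwise or degenerate loop (shoelace area ", signif(a, 3), ")")
    n <- nrow(xy)
    j <- c(2:n, 1)
    per <- sum(sqrt((xy[j, 1] - xy[, 1])^2 + (xy[j, 2] - xy[, 2])^2))
    cr <- xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]
    tibble::tibble(
      cell_id = mesh$cell_id[i], area = a, perimeter = per,
      neighbour_count = n,
      centroid_x = sum((xy[, 1] + xy[j, 1]) * cr) / (6 * a),
      centroid_y = sum((xy[, 2] + xy[j, 2]) * cr) / (6 * a),
      shape_index = per / sqrt(a)
    )
  })
  dplyr::bind_rows(rows)
}

#' Edge table of a mesh
#'
#' Unique undirected edges (consecutive vertex pairs in cell loops) with
#' their length and multiplicity (1 = boundary edge, 2 = interior edge).
#'
#' @param mesh a [tissue_mesh()].
#' @return tibble with columns `v1`, `v2` (vertex indices, `v1 < v2`),
#'   `length`, `multiplicity`.
#' @export
mesh_edges <- function(mesh) {
  pairs <- do.call(rbind, lapply(mesh$cells, function(L) {
    n <- length(L)
    cbind(L, L[c(2:n, 1)])
  }))
  a <- pmin(pairs[, 1], pairs[, 2])
  b <- pmax(pairs[, 1], pairs[, 2])
  key <- paste(a, b)
  tab <- table(key)
  first <- !duplicated(key)
  ua <- a[first]; ub <- b[first]; ukey <- key[first]
  len <- sqrt((mesh$vertices[ua, 1] - mesh$vertices[ub, 1])^2 +
              (mesh$vertices[ua, 2] - mesh$vertices[ub, 2])^2)
  tibble::tibble(v1 = ua, v2 = ub, length = len,
                 multiplicity = as.integer(tab[ukey]))
}

#' Check mesh invariants
#'
#' Validates the tessellation: all loop indices in range, loops simple
#' (non-self-intersecting) and counter-clockwise, every edge shared by at
#' most two cells, and every interior vertex a tri-junction (degree 3).
#' Boundary vertices (incident to an edge used by a single cell) may have
#' degree 2 or 3.
#'
#' @param mesh a [tissue_mesh()].
#' @return `check_mesh()` returns a character vector of problems (empty when
#'   valid); `validate_mesh()` errors on the first problem and returns the
#'   mesh invisibly otherwise.
#' @export
check_mesh <- function(mesh) {
  probs <- character(0)
  nv <- nrow(mesh$vertices)
  for (i in seq_along(mesh$cells)) {
    L <- mesh$cells[[i]]
    if (any(L < 1L | L > nv)) {
      probs <- c(probs, sprintf("cell %d: vertex index out of range", mesh$cell_id[i]))
      next
    }
    if (anyDuplicated(L))
      probs <- c(probs, sprintf("cell %d: repeated vertex in loop", mesh$cell_id[i]))
    xy <- mesh$vertices[L, , drop = FALSE]
    if (shoelace_area(xy) <= 0)
      probs <- c(probs, sprintf("cell %d: loop not counter-clockwise", mesh$cell_id[i]))
    if (self_intersects(xy))
      probs <- c(probs, sprintf("cell %d: self-intersecting loop", mesh$cell_id[i]))
  }
  ed <- mesh_edges(mesh)
  if (any(ed$multiplicity > 2))
    probs <- c(probs, "an edge is shared by more than two cells")
  deg <- tabulate(c(ed$v1, ed$v2), nbins = nv)
  on_boundary <- rep(FALSE, nv)
  bd <- ed[ed$multiplicity == 1, ]
  on_boundary[c(bd$v1, bd$v2)] <- TRUE
  bad <- which(!on_boundary & deg != 3)
  if (length(bad))
    probs <- c(probs, sprintf("interior vertex %s has degree != 3",
                              paste(bad, collapse = ",")))
  probs
}

#' @rdname check_mesh
#' @export
validate_mesh <- function(mesh) {
  probs <- check_mesh(mesh)
  if (length(probs)) stop("invalid mesh: ", probs[[1]])
  invisible(mesh)
}

# O(n^2) segment-pair test per loop; meshes are small wherever this runs.
self_intersects <- function(xy) {
  n <- nrow(xy)
  if (n < 4) return(FALSE)
  j <- c(2:n, 1)
  segs <- cbind(xy, xy[j, , drop = FALSE])
  for (p in 1:(n - 1)) {
    for (q in (p + 1):n) {
      if (q == p || j[p] == q || j[q] == p) next  # shared endpoint
      if (segments_cross(segs[p, ], segs[q, ])) return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(s1, s2) {
  d1 <- cross2(s2[3] - s2[1], s2[4] - s2[2], s1[1] - s2[1], s1[2] - s2[2])
  d2 <- cross2(s2[3] - s2[1], s2[4] - s2[2], s1[3] - s2[1], s1[4] - s2[2])
  d3 <- cross2(s1[3] - s1[1], s1[4] - s1[2], s2[1] - s1[1], s2[2] - s1[2])
  d4 <- cross2(s1[3] - s1[1], s1[4] - s1[2], s2[3] - s1[1], s2[4] - s1[2])
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

cross2 <- function(ax, ay, bx, by) ax * by - ay * bx
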