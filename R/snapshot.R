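#' Write / read a mesh snapshot
#'
#' Snapshots are JSON files with keys `time`, `vertices` (list of `[x, y]`
#' pairs at full double precision), and `cells` (list of objects with `id`,
#' `loop` (1-based vertex indices), `birth_time`, `tc`, `parent_id`), plus
#' `next_vertex_id` / `next_cell_id` so that id allocation survives a
#' round-trip.  The round-trip is lossless: positions are serialised with
#' 17 significant digits, which recovers every double bit-for-bit.
#'
#' @param mesh a [tissue_mesh()].
#' @param path file path.
#' @return `write_snapshot()` returns `path` invisibly; `read_snapshot()`
#'   returns a [tissue_mesh()].
#' @export
write_snapshot <- function(mesh, path) {
  stopifnot(inherits(mesh, "tissue_mesh"))
  obj <- list(
    time = mesh$time,
    vertices = unname(apply(mesh$vertices, 1, function(r) as.list(r),
                            simplify = FALSE)),
    vertex_id = as.list(mesh$vertex_id),
    cells = lapply(seq_along(mesh$cells), function(i) list(
      id = mesh$cell_id[i],
      loop = as.list(mesh$cells[[i]]),
      birth_time = mesh$birth_time[i],
      # JSON has no Inf: a mechanics-only cell (tc = Inf) is stored as null
      tc = if (is.finite(mesh$tc[i])) mesh$tc[i] else NULL,
      parent_id = mesh$parent_id[i]
    )),
    next_vertex_id = mesh$next_vertex_id,
    next_cell_id = mesh$next_cell_id
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                           null = "null", na = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("snapshot parse failure: ", conditionMessage(e)))
  for (field in c("time", "vertices", "cells"))
    if (is.null(obj[[field]]))
      stop("snapshot parse error: missing required field `", field, "`")
  verts <- do.call(rbind, lapply(obj$vertices, function(v) {
    if (length(v) != 2) stop("snapshot parse error: malformed entry in `vertices`")
    c(v[[1]], v[[2]])
  }))
  nc <- length(obj$cells)
  loops <- vector("list", nc)
  cid <- integer(nc); birth <- double(nc); tc <- double(nc); par <- integer(nc)
  for (i in seq_len(nc)) {
    cl <- obj$cells[[i]]
    for (field in c("id", "loop", "birth_time"))
      if (is.null(cl[[field]]))
        stop("snapshot parse error: missing required field `cells[[", i, "]]$", field, "`")
    loops[[i]] <- vapply(cl$loop, as.integer, integer(1))
    cid[i] <- as.integer(cl$id)
    birth[i] <- as.double(cl$birth_time)
    tc[i] <- if (is.null(cl$tc) || is.na(suppressWarnings(as.double(cl$tc)))) Inf else as.double(cl$tc)
    par[i] <- if (is.null(cl$parent_id)) NA_integer_ else as.integer(cl$parent_id)
  }
  m <- tissue_mesh(verts, loops, time = as.double(obj$time),
                   birth_time = birth, tc = tc, parent_id = par)
  m$cell_id <- cid
  if (!is.null(obj$vertex_id))
    m$vertex_id <- vapply(obj$vertex_id, as.integer, integer(1))
  if (!is.null(obj$next_vertex_id)) m$next_vertex_id <- as.integer(obj$next_vertex_id)
  if (!is.null(obj$next_cell_id)) m$next_cell_id <- as.integer(obj$next_cell_id)
  m
}
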