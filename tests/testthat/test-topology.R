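test_that("T1 swaps adjacency on the pinwheel fixture", {
  m <- pinwheel_mesh()
  sides_before <- sort(lengths(m$cells))
  r <- apply_T1(m, 1, 2)
  expect_true(r$applied)
  expect_length(check_mesh(r$mesh), 0)
  # the two cells that shared the edge lose a side; the flanking pair gains
  expect_equal(sort(lengths(r$mesh$cells)), sides_before)
  sides <- lengths(r$mesh$cells)
  expect_equal(sides[c(1, 3)], c(3L, 3L))  # E and W lost the edge
  expect_equal(sides[c(2, 4)], c(4L, 4L))  # N and S gained it
  # new edge has the prescribed length
  ed <- mesh_edges(r$mesh)
  central <- ed[(ed$v1 == 1 & ed$v2 == 2), ]
  expect_equal(central$length, topo_params()$l_new, tolerance = 1e-12)
  # local move: total area barely changes
  expect_lt(abs(sum(cell_geometry(r$mesh)$area) -
                  sum(cell_geometry(m)$area)) / sum(cell_geometry(m)$area),
            1e-6)
})

test_that("applying T1 twice restores the original adjacency", {
  m <- pinwheel_mesh()
  r1 <- apply_T1(m, 1, 2)
  r2 <- apply_T1(r1$mesh, 1, 2)
  expect_true(r2$applied)
  expect_equal(lengths(r2$mesh$cells), lengths(m$cells))
  # same unordered cell-adjacency relation as the start (vertex labels of the
  # junction pair may swap; the T1 inverse restores which cells touch)
  adjacency <- function(mm) {
    e <- mesh_edges(mm)
    shared <- e[e$multiplicity == 2, ]
    apply(shared, 1, function(ed) {
      touching <- which(vapply(mm$cells, function(L)
        all(c(ed[["v1"]], ed[["v2"]]) %in% L), logical(1)))
      paste(sort(mm$cell_id[touching]), collapse = "-")
    })
  }
  expect_setequal(adjacency(r2$mesh), adjacency(m))
})

test_that("T1 refuses boundary edges and reports why", {
  m <- pinwheel_mesh()
  r <- apply_T1(m, 3, 4)  # outer edge of cell E
  expect_false(r$applied)
  expect_match(r$reason, "interior|third cell")
})

test_that("T2 collapses a small interior triangle to a tri-junction", {
  m <- triangle_in_triangle_mesh()
  nv0 <- nrow(m$vertices)
  r <- apply_T2(m, cell_id = 0)
  expect_true(r$applied)
  expect_equal(r$kind, "T2")
  expect_equal(length(r$mesh$cells), 3)
  expect_equal(nrow(r$mesh$vertices), nv0 - 2)  # 3 vertices -> 1
  expect_true(all(lengths(r$mesh$cells) == 3))  # each neighbour lost a side
  expect_length(check_mesh(r$mesh), 0)
  # replacement vertex sits at the triangle centroid
  tri_centroid <- colMeans(m$vertices[m$cells[[1]], ])
  newv <- r$mesh$vertices[r$mesh$vertex_id == max(r$mesh$vertex_id), ]
  expect_equal(unname(newv), unname(tri_centroid), tolerance = 1e-9)
})

test_that("T2 refuses cells that are not triangles", {
  m <- pinwheel_mesh()
  r <- apply_T2(m, cell_id = 0)  # a quad
  expect_false(r$applied)
  expect_match(r$reason, "3-sided")
})

test_that("sweep is the identity on a clean mesh and resolves a short edge", {
  clean <- build_hexagonal_lattice(7)
  s <- sweep_topology(clean)
  expect_equal(nrow(s$events), 0)
  expect_identical(s$mesh$cells, clean$cells)

  short <- pinwheel_mesh(h = 0.01)  # central edge length 0.02 < 0.05
  s2 <- sweep_topology(short)
  expect_equal(sum(s2$events$kind == "T1"), 1)
  expect_length(check_mesh(s2$mesh), 0)

  # shrinking triangle: T2 fires during a sweep
  tri <- triangle_in_triangle_mesh(scale = 0.05)
  s3 <- sweep_topology(tri)
  expect_gte(sum(s3$events$kind == "T2"), 1)
  expect_equal(length(s3$mesh$cells), 3)
})

test_that("sweeps are deterministic", {
  m <- pinwheel_mesh(h = 0.01)
  s1 <- sweep_topology(m)
  s2 <- sweep_topology(m)
  expect_identical(s1$mesh$vertices, s2$mesh$vertices)
  expect_identical(s1$events, s2$events)
})

test_that("cell count identity N = N0 + divisions - T2 holds over a full run", {
  sim <- run_simulation(simulation_config(n_max = 250, seed = 9))
  expect_true(check_cell_count_identity(sim))
  # the identity holds at every snapshot, not just at the end
  ev <- sim$events
  for (t in sim$metrics$time) {
    n_t <- sim$metrics$n_cells[sim$metrics$time == t]
    expected <- sim$config$n0 +
      sum(ev$kind == "division" & ev$time <= t) -
      sum(ev$kind %in% c("T2", "peel") & ev$time <= t)
    expect_equal(n_t, expected)
  }
})
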