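test_that("hexagonal lattice has the requested cells with exact closed-form area", {
  m1 <- build_hexagonal_lattice(1, 1.0)
  g1 <- cell_geometry(m1)
  expect_equal(nrow(m1$vertices), 6)
  expect_equal(g1$area, 3 * sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(g1$perimeter, 6)
  expect_equal(g1$neighbour_count, 6L)

  # unit-area side: every cell area 1 to machine precision
  m <- build_hexagonal_lattice(100)
  geo <- cell_geometry(m)
  expect_equal(length(m$cells), 100)
  expect_true(all(abs(geo$area - 1) < 1e-12))
  expect_true(all(geo$neighbour_count == 6))
  expect_equal(sum(geo$area), 100, tolerance = 1e-9)
  expect_length(check_mesh(m), 0)

  # non-square counts are truncated row by row, never padded
  for (n in c(2, 5, 7, 13)) {
    expect_equal(length(build_hexagonal_lattice(n)$cells), n)
  }
})

test_that("lattice satisfies the planar Euler relation V - E + F = 2", {
  m <- build_hexagonal_lattice(7, 1.0)
  ed <- mesh_edges(m)
  V <- nrow(m$vertices)
  E <- nrow(ed)
  F <- length(m$cells) + 1  # count the outer face
  expect_equal(V - E + F, 2)
})

test_that("lattice construction rejects bad arguments", {
  expect_error(build_hexagonal_lattice(0), "positive")
  expect_error(build_hexagonal_lattice(-3), "positive")
  expect_error(build_hexagonal_lattice(5, side = 0), "positive")
})

test_that("cell_geometry matches closed forms and enforces orientation", {
  sq <- tissue_mesh(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), list(1:4))
  g <- cell_geometry(sq)
  expect_equal(g$area, 1)
  expect_equal(g$perimeter, 4)
  expect_equal(g$neighbour_count, 4L)
  expect_equal(g$shape_index, 4)

  hexa <- build_hexagonal_lattice(1, 1.0)
  expect_equal(cell_geometry(hexa)$area, 2.598076, tolerance = 1e-6)

  # the constructor normalises CW input ...
  cw <- tissue_mesh(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), list(4:1))
  expect_equal(cell_geometry(cw)$area, 1)
  # ... but geometry on a mesh whose loop was flipped post hoc errors
  bad <- sq
  bad$cells[[1]] <- rev(bad$cells[[1]])
  expect_error(cell_geometry(bad), "clockwise")
  expect_error(cell_geometry(sq, cell_id = 99), "unknown cell_id")
})

test_that("mesh validator flags broken meshes and passes good ones", {
  m <- build_hexagonal_lattice(12)
  expect_silent(validate_mesh(m))

  bad <- m
  bad$cells[[3]] <- rev(bad$cells[[3]])
  expect_match(check_mesh(bad), "counter-clockwise", all = FALSE)

  # bow-tie: self-intersecting quad
  bow <- tissue_mesh(rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1)),
                     list(c(1, 2, 3, 4)))
  expect_match(check_mesh(bow), "self-intersecting", all = FALSE)
})

test_that("snapshot I/O round-trips a mesh bit-for-bit", {
  m <- jittered_patch(7, seed = 11)
  m$tc <- c(rep(400, 3), rep(Inf, 4))
  m$birth_time <- as.double(seq(0, 6))
  m$time <- 123.456
  path <- withr::local_tempfile(fileext = ".json")
  write_snapshot(m, path)
  r <- read_snapshot(path)
  expect_identical(r$vertices, m$vertices)
  expect_identical(r$cells, m$cells)
  expect_identical(r$cell_id, m$cell_id)
  expect_identical(r$birth_time, m$birth_time)
  expect_identical(r$tc, m$tc)
  expect_identical(r$time, m$time)
  expect_identical(r$next_cell_id, m$next_cell_id)

  # 100-cell lattice snapshot: 100 loops, all hexagons
  m100 <- build_hexagonal_lattice(100)
  p2 <- withr::local_tempfile(fileext = ".json")
  write_snapshot(m100, p2)
  r100 <- read_snapshot(p2)
  expect_equal(length(r100$cells), 100)
  expect_true(all(lengths(r100$cells) == 6))
})

test_that("snapshot reader names the offending field", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"time": 0, "vertices": [[0,0],[1,0],[0,1]]}', path)
  expect_error(read_snapshot(path), "cells")
  writeLines('{"vertices": [], "cells": []}', path)
  expect_error(read_snapshot(path), "time")
  writeLines('{"time": 0, "vertices": [[0,0]], "cells": [{"id": 1}]}', path)
  expect_error(read_snapshot(path), "loop")
  writeLines("not json at all {", path)
  expect_error(read_snapshot(path), "parse")
})
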