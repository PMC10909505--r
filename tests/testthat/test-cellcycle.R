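test_that("intrinsic cycle lengths follow the shifted-exponential law", {
  set.seed(101)
  # epsilon = 1: degenerate at Tc
  expect_equal(sample_tc(50, cycle_params(Tc = 388, epsilon = 1)),
               rep(388, 50))
  # standard parameters: mean Tc, support bounded below by eps * Tc
  p <- cycle_params(Tc = 388, epsilon = 0.8)
  x <- sample_tc(1e5, p)
  expect_gte(min(x), 0.8 * 388)
  expect_lt(abs(mean(x) - 388), 3 * (0.2 * 388) / sqrt(1e5))
  expect_equal(sd(x), 0.2 * 388, tolerance = 0.05)
  # epsilon = 0: pure exponential of mean Tc
  y <- sample_tc(1e5, cycle_params(Tc = 1, epsilon = 0))
  ks <- suppressWarnings(ks.test(y, "pexp", 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("target-area schedule is piecewise with a clamp at A_f", {
  expect_equal(target_area(0, 388), 1)
  expect_equal(target_area(100, 388), 1)          # below tc/2
  expect_equal(target_area(388, 388, A_f = 2), 2) # 2t/tc at t = tc
  expect_equal(target_area(0.75 * 388, 388), 1.5)
  expect_equal(target_area(1.5 * 388, 388, A_f = 2), 2)  # clamped
  expect_error(target_area(-1, 388), "non-negative")
})

test_that("division readiness combines the age and critical-area gates", {
  p <- cycle_params()  # A_c = 0.78 * 2 = 1.56
  expect_equal(p$A_c, 1.56)
  expect_true(division_ready(age = 400, tc = 400, area = 1.6, p))
  expect_false(division_ready(age = 400, tc = 400, area = 1.0, p))
  expect_false(division_ready(age = 399, tc = 400, area = 1.6, p))
  # ablation: no area requirement
  off <- cycle_params(A_c = 0, with_area_gate = FALSE)
  expect_true(division_ready(age = 400, tc = 400, area = 1.0, off))
  # ages below eps * Tc can never be ready because tc >= eps * Tc
  tcs <- sample_tc(100, p)
  expect_false(any(division_ready(age = 0.8 * 388 - 1, tc = tcs, area = 2, p)))
})

test_that("division conserves area and preserves mesh validity", {
  set.seed(21)
  for (trial in 1:5) {
    m <- jittered_patch(7, jitter = 0.03)
    before <- sum(cell_geometry(m)$area)
    target <- cell_geometry(m, 3)$area
    d <- divide_cell(m, cell_id = 3)
    expect_true(d$applied)
    expect_equal(length(d$mesh$cells), 8)
    expect_length(check_mesh(d$mesh), 0)
    after <- cell_geometry(d$mesh)
    expect_equal(sum(after$area), before, tolerance = 1e-10)
    # daughters carry the parent area between them
    kids <- after[after$cell_id %in% c(d$events$cell2, d$events$cell3), ]
    expect_equal(sum(kids$area), target, tolerance = 1e-10)
  }
})

test_that("daughters get fresh state and lineage bookkeeping", {
  set.seed(22)
  m <- build_hexagonal_lattice(1, 1.0)
  m$time <- 500
  m$birth_time <- 0
  d <- divide_cell(m, cell_id = 0, params = cycle_params())
  expect_true(d$applied)
  expect_equal(length(d$mesh$cells), 2)
  st <- cell_states(d$mesh)
  expect_equal(st$birth_time, c(500, 500))
  expect_equal(st$parent_id, c(0L, 0L))
  expect_true(all(st$tc >= 0.8 * 388))
  expect_false(st$cell_id[1] == st$cell_id[2])
  # ids are fresh, never reused
  expect_true(all(st$cell_id > 0))
  ev <- d$events
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "division")
  expect_equal(ev$parent_age, 500)
  expect_equal(ev$parent_area, 3 * sqrt(3) / 2, tolerance = 1e-12)
})

test_that("short-axis rule splits an elongated cell across its long axis", {
  set.seed(23)
  # stretched hexagon, long axis = x: the split line should be near-vertical,
  # giving daughters of similar area
  m <- build_hexagonal_lattice(1, 1.0)
  m$vertices[, 1] <- m$vertices[, 1] * 3
  d <- divide_cell(m, cell_id = 0, rule = "short_axis")
  expect_true(d$applied)
  g <- cell_geometry(d$mesh)
  expect_equal(g$area[1], g$area[2], tolerance = 1e-6)
  cents <- abs(g$centroid_x)
  expect_true(all(cents > 0.5))  # daughters left and right of the cut
})
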