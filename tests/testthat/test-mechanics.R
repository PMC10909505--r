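table1 <- mech_params()  # K = 1, Lambda = 0.05, Gamma = 0.02

test_that("energy of a single regular hexagon matches direct substitution", {
  m <- build_hexagonal_lattice(1, 1.0)
  # K/2 (A-1)^2 + Gamma/2 L^2 + Lambda L with A = 3*sqrt(3)/2, L = 6
  expect_equal(total_energy(m, 1, table1),
               0.5 * (3 * sqrt(3) / 2 - 1)^2 + 0.01 * 36 + 0.05 * 6,
               tolerance = 1e-12)
  expect_equal(total_energy(m, 1, table1), hexagon_energy(1, 1),
               tolerance = 1e-12)
})

test_that("energy vanishes in the degenerate limits", {
  m <- jittered_patch(7, seed = 2)
  zero <- mech_params(K = 1e-300, Lambda = 0, Gamma = 0)  # K must stay > 0
  expect_equal(total_energy(m, 1, zero), 0, tolerance = 1e-12)
  # at A = A0 with no tension or contractility the elastic minimum is 0
  m0 <- build_hexagonal_lattice(9)
  elastic <- mech_params(K = 1, Lambda = 0, Gamma = 0)
  expect_equal(total_energy(m0, 1, elastic), 0, tolerance = 1e-18)
})

test_that("energy requires a target per cell", {
  m <- build_hexagonal_lattice(4)
  expect_error(total_energy(m, c(1, 1), table1), "every cell")
})

test_that("analytic forces equal finite differences of the energy", {
  for (seed in 1:5) {
    m <- jittered_patch(7, jitter = 0.04, seed = seed)
    tg <- runif(7, 0.8, 1.6)
    F <- forces(m, tg, table1)
    expect_lt(max(abs(F - fd_forces(m, tg, table1))), 1e-5)
  }
})

test_that("total force is zero by translation invariance, and translations leave forces unchanged", {
  m <- jittered_patch(12, seed = 3)
  F <- forces(m, 1.2, table1)
  expect_lt(max(abs(colSums(F))), 1e-10)
  m2 <- m
  m2$vertices <- m2$vertices + rep(c(3.7, -1.9), each = nrow(m2$vertices))
  expect_equal(forces(m2, 1.2, table1), F, tolerance = 1e-9)
})

test_that("a relaxed single hexagon sits at the 1D-oracle minimum with vanishing forces", {
  s_star <- hexagon_optimal_side(1)
  a_star <- 3 * sqrt(3) / 2 * s_star^2
  m <- build_hexagonal_lattice(1, 1.0)
  r <- relax_mesh(m, 1, table1, tol = 1e-9, max_steps = 2e5)
  expect_true(attr(r, "converged"))
  expect_equal(cell_geometry(r)$area, a_star, tolerance = 1e-4)
  expect_lt(max(abs(forces(r, 1, table1))), 1e-8)
})

test_that("relax is a no-op on a converged mesh and with infinite tolerance", {
  m <- build_hexagonal_lattice(1, 1.0)
  r <- relax_mesh(m, 1, table1, tol = 1e-9, max_steps = 2e5)
  r2 <- relax_mesh(r, 1, table1, tol = 1e-8)
  expect_lte(attr(r2, "steps"), 1)
  r3 <- relax_mesh(m, 1, table1, tol = Inf)
  expect_identical(r3$vertices, m$vertices)
})

test_that("step obeys the overdamped update rule", {
  m <- jittered_patch(5, seed = 4)
  F <- forces(m, 1, table1)
  stepped <- step_mesh(m, 1, table1)
  expect_equal(stepped$vertices,
               m$vertices + (table1$dt / table1$gamma) * F, tolerance = 1e-14)
  expect_equal(stepped$time, m$time + table1$dt)
  # zero forces: mesh unchanged
  z <- mech_params(K = 1e-300, Lambda = 0, Gamma = 0, dt = 0.05)
  expect_equal(step_mesh(m, 1, z)$vertices, m$vertices, tolerance = 1e-12)
})

test_that("one step at (gamma = 2, dt) equals one at (gamma = 1, dt/2)", {
  m <- jittered_patch(5, seed = 5)
  p2 <- mech_params(gamma = 2, dt = 0.05)
  p1 <- mech_params(gamma = 1, dt = 0.025)
  expect_identical(step_mesh(m, 1, p2)$vertices, step_mesh(m, 1, p1)$vertices)
})

test_that("gamma-time rescaling symmetry holds for static-target trajectories", {
  # with static targets the dynamics depend on dt/gamma only, so a run at
  # (gamma, dt) reproduces one at (1, dt/gamma) sampled at rescaled times
  g <- 3.7
  run_one <- function(gamma, dt, n) {
    m <- jittered_patch(7, jitter = 0.05, seed = 6)
    p <- mech_params(gamma = gamma, dt = dt)
    for (i in seq_len(n)) m <- step_mesh(m, 1, p)
    m$vertices
  }
  expect_equal(run_one(g, 0.05, 40), run_one(1, 0.05 / g, 40),
               tolerance = 1e-8)
})

test_that("energy is non-increasing along relaxation with static targets", {
  m <- jittered_patch(7, jitter = 0.08, seed = 7)
  p <- mech_params(gamma = 1, dt = 0.01)  # dt = 0.01 * gamma / K
  e <- total_energy(m, 1, p)
  for (i in 1:200) {
    m <- step_mesh(m, 1, p)
    e2 <- total_energy(m, 1, p)
    expect_lte(e2, e + 1e-12)
    e <- e2
  }
})
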