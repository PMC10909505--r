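test_that("k_det is ln 2 over the mean cycle duration", {
  expect_equal(k_det(388), log(2) / 388)
  expect_equal(k_det(log(2)), 1)
  expect_equal(k_det(2 * 388), k_det(388) / 2)
  expect_error(k_det(0), "positive")
})

test_that("division hazard is constant for the memoryless cycle and zero before the support", {
  d0 <- cycle_distribution(epsilon = 0, Tc = 1)
  taus <- c(0, 0.3, 1.7, 4)
  delta <- 1e-4
  haz <- division_hazard(d0, taus, delta) / delta
  expect_equal(haz, rep(1, 4), tolerance = 1e-3)

  d8 <- cycle_distribution(epsilon = 0.8, Tc = 1)
  expect_equal(division_hazard(d8, c(0, 0.5, 0.79), 0.005), rep(0, 3))
  expect_error(division_hazard(cycle_distribution(1, 1), 1.5, 0.01),
               "undefined")
})

test_that("finite-window hazard matches -delta dlog(1 - G)/dtau to O(delta^2)", {
  d <- cycle_distribution(epsilon = 0.6, Tc = 2)
  tau <- 1.7
  for (delta in c(0.02, 0.01, 0.005)) {
    g <- division_hazard(d, tau, delta)
    exact <- -(log(1 - cycle_cdf(d, tau + delta)) -
                 log(1 - cycle_cdf(d, tau)))
    # g = 1 - exp(-exact); agreement to O(delta^2)
    expect_equal(g, exact, tolerance = delta * 2)
  }
})

test_that("stationary age density normalises, matches the step form at epsilon = 1, and has f(0) = 2k", {
  d1 <- cycle_distribution(epsilon = 1, Tc = 1)
  k <- log(2)
  taus <- seq(0, 0.99, length.out = 50)
  f <- stationary_age_density(d1, k, taus)
  expect_equal(f, 2 * k * exp(-k * taus), tolerance = 1e-10)
  expect_equal(stationary_age_density(d1, k, 1.5), 0)
  # numeric normalisation
  grid <- seq(0, 1, length.out = 20001)
  expect_equal(sum(stationary_age_density(d1, k, grid)) * (grid[2] - grid[1]),
               1, tolerance = 1e-3)

  # f(0) = 2 k_sto at the Euler-Lotka rate, for a non-trivial distribution
  d <- cycle_distribution(epsilon = 0.8, Tc = 1)
  ks <- solve_euler_lotka(d)
  expect_equal(stationary_age_density(d, ks, 0), 2 * ks, tolerance = 1e-9)
  # CDF is consistent with the density
  expect_equal(stationary_age_cdf(d, ks, 10), 1, tolerance = 1e-9)
  mid <- stationary_age_cdf(d, ks, 0.5)
  num <- sum(stationary_age_density(d, ks, seq(0, 0.5, 1e-4))) * 1e-4
  expect_equal(mid, num, tolerance = 1e-3)
})

test_that("Euler-Lotka solver reproduces the closed-form limits", {
  # epsilon = 1 -> ln2 / Tc; epsilon = 0 -> 1 / Tc (upper bound)
  expect_equal(solve_euler_lotka(cycle_distribution(1, 388)), log(2) / 388,
               tolerance = 1e-9)
  expect_equal(solve_euler_lotka(cycle_distribution(0, 388)), 1 / 388,
               tolerance = 1e-9)
  expect_equal(solve_euler_lotka(cycle_distribution(0, 1)), 1,
               tolerance = 1e-10)
})

test_that("k_sto interpolates monotonically between 1/Tc and ln2/Tc", {
  eps <- seq(0, 1, by = 0.1)
  ks <- vapply(eps, function(e) solve_euler_lotka(cycle_distribution(e, 1)),
               double(1))
  expect_true(all(diff(ks) < 0))
  expect_true(all(ks >= log(2) - 1e-9 & ks <= 1 + 1e-9))
  # stochasticity speeds growth at fixed mean: k_sto >= k_det, equality at eps = 1
  expect_true(all(ks >= log(2) - 1e-9))
  expect_equal(ks[11], log(2), tolerance = 1e-9)
})

test_that("empirical Euler-Lotka converges to the parametric solution", {
  set.seed(31)
  d <- cycle_distribution(epsilon = 0.8, Tc = 1)
  x <- sample_tc(1e5, cycle_params(Tc = 1, epsilon = 0.8))
  ke <- solve_euler_lotka(empirical_cycle_distribution(x))
  expect_equal(ke, solve_euler_lotka(d), tolerance = 0.01)
})

test_that("branching process doubles synchronously when epsilon = 1", {
  set.seed(32)
  bp <- branching_process_simulate(cycle_params(Tc = 1, epsilon = 1),
                                   t_end = 4.5, n0 = 1)
  tr <- bp$trajectory
  expect_equal(tr$n_cells, 2^floor(tr$time / 1))
  expect_false(bp$capped)
})

test_that("branching-process durations replicate the sampling law", {
  set.seed(33)
  bp <- branching_process_simulate(cycle_params(Tc = 1, epsilon = 0.8),
                                   t_end = 8, n0 = 200)
  expect_gte(min(bp$durations), 0.8)
  expect_equal(mean(bp$durations), 1, tolerance = 0.05)
})

test_that("branching-process ages converge to the stationary age density", {
  # the initially synchronous population rings for several generations; by
  # twelve mean cycles the snapshot ages are statistically indistinguishable
  # from the stationary density (KS at the 1% level, n = 1e4)
  set.seed(1)
  d <- cycle_distribution(epsilon = 0.8, Tc = 1)
  k <- solve_euler_lotka(d)
  bp <- branching_process_simulate(cycle_params(Tc = 1, epsilon = 0.8),
                                   t_end = 12, n0 = 500, cap = 5e6)
  a <- sample(bp$ages, 1e4)
  ks <- suppressWarnings(ks.test(a, function(q) stationary_age_cdf(d, k, q)))
  expect_gt(ks$p.value, 0.01)
})

test_that("age-structure estimator recovers a known rate from synthetic stationary ages", {
  set.seed(34)
  d <- cycle_distribution(epsilon = 0.8, Tc = 1)
  k <- solve_euler_lotka(d)
  # inverse-CDF sampling from the stationary age density
  u <- runif(5000)
  grid <- seq(0, 6, length.out = 4001)
  cdf <- stationary_age_cdf(d, k, grid)
  ages <- approx(cdf, grid, xout = u, rule = 2)$y
  est <- ksto_from_age_structure(ages, delta = 0.02)
  expect_lt(abs(est$estimate - k), 2 * est$se)
})

test_that("age-structure estimator handles degenerate input", {
  expect_warning(est <- ksto_from_age_structure(rep(5, 200), delta = 0.01),
                 "newborn")
  expect_equal(est$estimate, 0)
  expect_match(est$flag, "no newborns")
  expect_error(ksto_from_age_structure(1:50, delta = 0.1), "at least 100")
})

test_that("exponential fit recovers an exact synthetic rate", {
  tr <- tibble::tibble(time = seq(0, 1000, by = 50),
                       n_cells = 100 * exp(0.002 * time))
  est <- fit_growth_rate(tr)
  expect_equal(est$estimate, 0.002, tolerance = 1e-10)
  expect_equal(est$method, "exp_fit")
  # non-growing trajectories are flagged, not errors
  flat <- tibble::tibble(time = seq(0, 1000, by = 50),
                         n_cells = 100 * exp(-1e-4 * time))
  expect_equal(fit_growth_rate(flat)$flag, "non-growing trajectory")
})

test_that("tidiers return well-formed tibbles", {
  g <- growth_estimate(0.7, 0.01, "exp_fit", 10)
  td <- tidy(g)
  expect_named(td, c("term", "estimate", "std.error", "method"))
  expect_equal(td$estimate, 0.7)
  gl <- glance(g)
  expect_equal(gl$n, 10L)
})
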