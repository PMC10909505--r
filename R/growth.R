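#' Cell-cycle duration distributions
#'
#' Growth theory works with the distribution `P(tau)` of cell-cycle
#' durations, either in parametric form (the shifted-exponential intrinsic
#' family: deterministic fraction `epsilon`, mean `Tc`) or as an empirical
#' sample of observed durations.  The object exposes the density, the CDF
#' `G`, the mean, and the Laplace transform `E[exp(-k tau)]` that the
#' Euler--Lotka equation is written in.
#'
#' @param epsilon deterministic fraction in `[0, 1]`.
#' @param Tc mean cycle duration (> 0).
#' @param durations numeric vector of observed cycle durations (> 0).
#' @return an object of class `cycle_distribution`.
#' @export
cycle_distribution <- function(epsilon, Tc) {
  stopifnot(epsilon >= 0, epsilon <= 1, Tc > 0)
  structure(list(kind = "parametric", epsilon = epsilon, Tc = Tc),
            class = "cycle_distribution")
}

#' @rdname cycle_distribution
#' @export
empirical_cycle_distribution <- function(durations) {
  durations <- as.double(durations[is.finite(durations)])
  stopifnot(length(durations) >= 2, all(durations > 0))
  structure(list(kind = "empirical", durations = durations),
            class = "cycle_distribution")
}

#' @export
print.cycle_distribution <- function(x, ...) {
  if (x$kind == "parametric")
    cat(sprintf("<cycle_distribution> shifted exponential: epsilon = %g, Tc = %g\n",
                x$epsilon, x$Tc))
  else
    cat(sprintf("<cycle_distribution> empirical, n = %d, mean = %.4g\n",
                length(x$durations), mean(x$durations)))
  invisible(x)
}

#' @rdname cycle_distribution
#' @param dist a `cycle_distribution`.
#' @param tau age / duration values.
#' @export
cycle_cdf <- function(dist, tau) {
  if (dist$kind == "parametric") {
    eps <- dist$epsilon; Tc <- dist$Tc
    if (eps >= 1) return(as.double(tau >= Tc))
    r <- 1 / ((1 - eps) * Tc)
    ifelse(tau < eps * Tc, 0, 1 - exp(-r * (tau - eps * Tc)))
  } else {
    vapply(tau, function(t) mean(dist$durations <= t), double(1))
  }
}

#' @rdname cycle_distribution
#' @export
cycle_density <- function(dist, tau) {
  if (dist$kind != "parametric")
    stop("density is only defined for the parametric family; use cycle_cdf()")
  eps <- dist$epsilon; Tc <- dist$Tc
  if (eps >= 1) stop("epsilon = 1 is a point mass; it has no density")
  r <- 1 / ((1 - eps) * Tc)
  ifelse(tau < eps * Tc, 0, r * exp(-r * (tau - eps * Tc)))
}

#' @rdname cycle_distribution
#' @export
cycle_mean <- function(dist) {
  if (dist$kind == "parametric") dist$Tc else mean(dist$durations)
}

#' @rdname cycle_distribution
#' @param k non-negative rate at which to evaluate `E[exp(-k tau)]`.
#' @export
cycle_laplace <- function(dist, k) {
  if (dist$kind == "parametric") {
    eps <- dist$epsilon; Tc <- dist$Tc
    exp(-k * eps * Tc) / (1 + k * (1 - eps) * Tc)
  } else {
    vapply(k, function(kk) mean(exp(-kk * dist$durations)), double(1))
  }
}

#' Deterministic growth rate from the mean cycle duration
#'
#' `k_det = ln(2) / mean_cycle`: the exponential rate of a population in
#' which every cell divides exactly at the mean duration.
#'
#' @param mean_cycle mean cell-cycle duration (> 0).
#' @return growth rate (1/time).
#' @export
k_det <- function(mean_cycle) {
  if (!is.numeric(mean_cycle) || any(mean_cycle <= 0))
    stop("`mean_cycle` must be positive")
  log(2) / mean_cycle
}

#' Conditional division probability (hazard) at a given age
#'
#' The probability that a cell that has survived to age `tau` divides in
#' `(tau, tau + delta]`:
#' \deqn{g_\delta(\tau) = \frac{G(\tau+\delta) - G(\tau)}{1 - G(\tau)},}
#' whose `delta -> 0` limit per unit time is the hazard `P(tau)/(1-G(tau))`.
#'
#' @param dist a [cycle_distribution()].
#' @param tau age (>= 0) at which the cell is known undivided.
#' @param delta window width (> 0).
#' @return probability in `[0, 1]`, vectorised over `tau`.
#' @export
division_hazard <- function(dist, tau, delta) {
  stopifnot(delta > 0)
  surv <- 1 - cycle_cdf(dist, tau)
  if (any(surv <= 0))
    stop("hazard undefined: age beyond the support of the cycle distribution (G = 1)")
  (cycle_cdf(dist, tau + delta) - cycle_cdf(dist, tau)) / surv
}

# \int_0^tau e^{-k u} (1 - G(u)) du, closed form per distribution kind.
age_density_integral <- function(dist, k, tau) {
  if (dist$kind == "parametric") {
    eps <- dist$epsilon; Tc <- dist$Tc
    e <- eps * Tc
    r <- if (eps >= 1) Inf else 1 / ((1 - eps) * Tc)
    pre <- (1 - exp(-k * pmin(tau, e))) / k
    extra <- ifelse(tau > e,
                    exp(-k * e) * (1 - exp(-(k + r) * (tau - e))) / (k + r),
                    0)
    pre + extra
  } else {
    d <- dist$durations
    vapply(tau, function(t) mean((1 - exp(-k * pmin(t, d))) / k), double(1))
  }
}

#' Stationary age density of an exponentially growing population
#'
#' In steady exponential growth at rate `k_sto` the density of cell ages is
#' \deqn{f(\tau) \propto (1 - G(\tau))\, e^{-k_{sto} \tau},}
#' the product of cycle survival and the exponential dilution of older
#' cohorts by newborns.  The normalising constant is
#' `(1 - E[exp(-k tau)]) / k`, so at the Euler--Lotka rate the density at
#' age zero equals `2 k_sto`.
#'
#' @param dist a [cycle_distribution()].
#' @param k_sto growth rate (> 0, or large enough that the density
#'   normalises).
#' @param tau ages at which to evaluate.
#' @return `stationary_age_density()`: normalised density values;
#'   `stationary_age_cdf()`: the corresponding CDF.  Both vectorised over
#'   `tau`.
#' @export
stationary_age_density <- function(dist, k_sto, tau) {
  Z <- age_normaliser(dist, k_sto)
  (1 - cycle_cdf(dist, tau)) * exp(-k_sto * tau) / Z
}

#' @rdname stationary_age_density
#' @export
stationary_age_cdf <- function(dist, k_sto, tau) {
  Z <- age_normaliser(dist, k_sto)
  pmin(1, age_density_integral(dist, k_sto, tau) / Z)
}

age_normaliser <- function(dist, k_sto) {
  if (!is.finite(k_sto) || k_sto <= 0)
    stop("the age density does not normalise for k_sto <= 0")
  (1 - cycle_laplace(dist, k_sto)) / k_sto
}

#' Solve the Euler--Lotka equation for the growth rate
#'
#' Finds the unique `k > 0` with
#' \deqn{\tfrac{1}{2} = \int_0^\infty e^{-k\tau} P(\tau)\, d\tau = E[e^{-k\tau}].}
#' For the parametric intrinsic family this is the transcendental equation
#' \eqn{1/2 = e^{-k\varepsilon T_c} / (1 + k(1-\varepsilon)T_c)}; for an
#' empirical sample the transform is the plain sample mean of
#' `exp(-k * tau_i)`.  The transform is strictly decreasing in `k` from 1,
#' so the root is unique; it is bracketed and found with [stats::uniroot()]
#' at tolerance `tol`.
#'
#' Limits of the parametric family: `epsilon = 1` gives `ln(2)/Tc`
#' (deterministic doubling) and `epsilon = 0` gives `1/Tc` (memoryless
#' cycle, the fastest growth at fixed mean).
#'
#' @param dist a [cycle_distribution()].
#' @param tol root tolerance (on `k * mean`).
#' @return growth rate `k_sto` (1/time).
#' @export
solve_euler_lotka <- function(dist, tol = 1e-12) {
  mu <- cycle_mean(dist)
  stopifnot(is.finite(mu), mu > 0)
  f <- function(k) cycle_laplace(dist, k) - 0.5
  hi <- 1 / mu
  it <- 0
  while (f(hi) > 0) {
    hi <- hi * 2
    it <- it + 1
    if (it > 60) stop("no Euler-Lotka root found in (0, ", signif(hi, 3), ")")
  }
  uniroot(f, lower = 0, upper = hi, tol = tol / mu)$root
}

#' Growth-rate estimate container
#'
#' Light S3 record for a growth-rate estimate with its standard error and
#' the method that produced it.  Supports [tidy()] and [glance()].
#'
#' @param estimate growth rate (1/time).
#' @param se standard error (may be `NA`).
#' @param method short method tag.
#' @param n sample / problem size behind the estimate.
#' @param flag optional character note (e.g. `"non-growing"`).
#' @return object of class `growth_estimate`.
#' @export
growth_estimate <- function(estimate, se = NA_real_, method = "unknown",
                            n = NA_integer_, flag = NA_character_) {
  structure(list(estimate = estimate, se = se, method = method,
                 n = as.integer(n), flag = flag),
            class = "growth_estimate")
}

#' @export
print.growth_estimate <- function(x, ...) {
  cat(sprintf("<growth_estimate> k = %.6g (se %.3g), method = %s, n = %d\n",
              x$estimate, x$se, x$method, x$n))
  if (!is.na(x$flag)) cat("  note:", x$flag, "\n")
  invisible(x)
}

#' Growth rate from the age structure of a single snapshot
#'
#' Uses the boundary identity `k_sto = N(t, 0) / (2 N(t))`: in steady
#' exponential growth, half the per-cell newborn density equals the growth
#' rate.  The newborn density is estimated as the fraction of ages below
#' `delta`, divided by `delta`.  If the window contains no newborns it is
#' doubled (at most three times, with a warning); if even the widened
#' window is empty the estimate is 0, flagged and with a warning.
#'
#' @param ages numeric vector of cell ages at one time point (n >= 100).
#' @param delta newborn window width; small relative to the mean age.  A
#'   sensible default is 2 percent of the mean cycle duration.
#' @param n_boot bootstrap replicates for the standard error.
#' @return a [growth_estimate()] (method `"age_structure"`) with a
#'   `delta_used` attribute.
#' @export
ksto_from_age_structure <- function(ages, delta, n_boot = 200) {
  ages <- as.double(ages[is.finite(ages)])
  if (length(ages) < 100)
    stop("need at least 100 ages for the age-structure estimator")
  stopifnot(delta > 0)
  d <- delta
  widened <- 0
  while (sum(ages < d) == 0 && widened < 3) {
    d <- 2 * d
    widened <- widened + 1
  }
  if (sum(ages < d) == 0) {
    warning("no cell younger than the (widened) newborn window; estimate is 0")
    out <- growth_estimate(0, 0, "age_structure", length(ages),
                           "no newborns below delta: estimate 0")
    attr(out, "delta_used") <- d
    return(out)
  }
  if (widened > 0)
    warning("newborn window widened from ", delta, " to ", d)
  est_fun <- function(a) 0.5 * mean(a < d) / d
  k <- est_fun(ages)
  boots <- vapply(seq_len(n_boot), function(b)
    est_fun(sample(ages, replace = TRUE)), double(1))
  out <- growth_estimate(k, sd(boots), "age_structure", length(ages))
  attr(out, "delta_used") <- d
  out
}

#' Exponential growth rate from a cell-count time series
#'
#' Least-squares slope of `log(N)` against time, the estimator for
#' `N(t) = N0 exp(k t)`.  Rows before `t_min` are dropped to exclude the
#' early transient.
#'
#' @param metrics data frame with columns `time` and `n_cells` (a metrics
#'   table from [run_simulation()] or a branching-process trajectory).
#' @param t_min drop snapshots earlier than this (default: keep all).
#' @return a [growth_estimate()] (method `"exp_fit"`); flagged when the
#'   trajectory is non-growing.
#' @export
fit_growth_rate <- function(metrics, t_min = -Inf) {
  d <- metrics[metrics$time >= t_min & metrics$n_cells > 0, , drop = FALSE]
  if (nrow(d) < 5) stop("need at least 5 snapshots to fit a growth rate")
  if (max(d$n_cells) < 2 * min(d$n_cells))
    warning("trajectory spans less than one doubling; rate is poorly constrained")
  fit <- lm(log(n_cells) ~ time, data = d)
  k <- unname(coef(fit)[2])
  se <- summary(fit)$coefficients[2, 2]
  flag <- if (k <= 0) "non-growing trajectory" else NA_character_
  growth_estimate(k, se, "exp_fit", nrow(d), flag)
}
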