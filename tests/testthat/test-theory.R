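# Closed-form theory: repertoire growth, clonal growth law, exponents,
# fluctuating-fitness densities, zero-insertion relaxation, neutral null.

test_that("mean total repertoire size follows the homeostatic growth curve", {
  p <- fig_formation()
  expect_equal(mean_total_size(0, p), 0)
  # saturation value (b0 + theta*C0)/d
  expect_equal(mean_total_size(1e6, p), (1e7 + 1e6) / 0.2, tolerance = 1e-12)
  expect_equal(mean_total_size(1e6, p), 5.5e7)
  # early growth is linear: relative error < 5% at t = 0.05/d
  t_small <- 0.05 / p$d
  expect_lt(abs(mean_total_size(t_small, p) / ((p$b0 + p$theta * p$C0) * t_small) - 1),
            0.05)
  # monotone increasing
  ts <- seq(0, 50, length.out = 200)
  expect_true(all(diff(mean_total_size(ts, p)) > 0))
  # d = 0 limit is linear growth
  p0 <- formation_params(b0 = 10, d = 0, theta = 1)
  expect_equal(mean_total_size(3, p0), 33)
})

test_that("clonal growth law matches its initial condition and early limit", {
  p <- fig_formation()
  expect_equal(clone_growth(0.3, 0.3, p), 1)
  expect_equal(clone_growth(0.3, 0.3, p, early_limit = TRUE), 1)
  # C0 * (t/ti)^(1/(1+gamma)) at gamma = 0.1: 10^(1/1.1)
  expect_equal(clone_growth(1, 0.1, p, early_limit = TRUE), 10^(1 / 1.1),
               tolerance = 1e-12)
  expect_equal(clone_growth(1, 0.1, p, early_limit = TRUE), 8.1113,
               tolerance = 1e-4)
  # full form converges to early form as d -> 0 at fixed t, ti
  for (d in c(0.02, 0.002)) {
    pd <- formation_params(b0 = 1e7, d = d, theta = 1e6)
    gap <- abs(clone_growth(1, 0.1, pd) /
                 clone_growth(1, 0.1, pd, early_limit = TRUE) - 1)
    expect_lt(gap, 1)  # finite
    if (d * 1 < 0.02) expect_lt(gap, 0.01)
  }
  expect_error(clone_growth(1, 0, p), "strictly positive")
  expect_error(clone_growth(0.1, 0.5, p), "t >= t_recruit")
})

test_that("formation exponent and crossover time are the stated functions of gamma", {
  expect_equal(formation_exponent(0), 1)
  expect_equal(formation_exponent(0.1), 1.1)
  expect_equal(formation_exponent(1), 2)
  p <- formation_params(b0 = 1e5, d = 0.2, theta = 1e4)  # gamma = 0.1
  expect_equal(crossover_time(p), log(11) / 0.2, tolerance = 1e-12)
  expect_equal(crossover_time(p), 11.99, tolerance = 1e-3)
  # gamma = 1/(e-1) makes 1 + 1/gamma = e, so t_star = 1/d exactly
  pe <- formation_params(b0 = 1, d = 1, theta = 1 / (exp(1) - 1))
  expect_equal(crossover_time(pe), 1, tolerance = 1e-12)
  # monotonically decreasing in gamma at fixed d
  ts <- sapply(c(0.05, 0.1, 0.5, 1, 2), function(g)
    crossover_time(formation_params(b0 = 1 / g, d = 0.2, theta = 1)))
  expect_true(all(diff(ts) < 0))
  expect_error(crossover_time(formation_params(b0 = 1, d = 0.2, theta = 0)),
               "gamma")
})

test_that("cytokine quasi-steady state has the saturating competition form", {
  cp <- cytokine_params(p = 1, q = 1, k = 1)
  expect_equal(cytokine_quasi_steady(0, cp), 1)  # p/q
  expect_equal(cytokine_quasi_steady(1, cp), 0.5)
  # S(N) * N -> p/k as N -> Inf
  expect_equal(cytokine_quasi_steady(1e9, cp) * 1e9, 1, tolerance = 1e-8)
})

test_that("the Green's function is the normal law with the stated moments", {
  fp <- study_fluct()
  q <- integrate(function(x) gbm_green(x, 0.5, 3, fp), -Inf, Inf,
                 rel.tol = 1e-10)
  expect_lt(abs(q$value - 1), 1e-8)
  m <- integrate(function(x) x * gbm_green(x, 0.5, 3, fp), -Inf, Inf,
                 rel.tol = 1e-10)$value
  expect_equal(m, 0.5 + fp$f0 * 3, tolerance = 1e-8)
  v <- integrate(function(x) (x - m)^2 * gbm_green(x, 0.5, 3, fp), -Inf, Inf,
                 rel.tol = 1e-10)$value
  expect_equal(v, 2 * fp$sigma2 * 3, tolerance = 1e-6)
  expect_error(gbm_green(0, 0, -1, fp), "positive")
})

test_that("finite-time fluctuating-fitness density matches the quadrature oracle", {
  fp <- study_fluct()
  T <- 30
  # independent oracle: integrate the Green's function over uniform clonal age
  quad <- function(x) integrate(function(t) gbm_green(x, 0, t, fp), 0, T,
                                rel.tol = 1e-11)$value / T
  xs <- c(-4, -1, -0.1, 0.2, 1.5, 4)
  expect_equal(fluct_density(xs, T, fp), vapply(xs, quad, numeric(1)),
               tolerance = 1e-9)
})

test_that("fluctuating-fitness density normalizes and approaches the steady-state tail", {
  for (tau in c(0.5, 5, 50)) {
    q <- integrate(function(x) fluct_density(x, rescaled = TRUE, tau = tau,
                                             alpha = 1.2),
                   -Inf, Inf, rel.tol = 1e-9)
    expect_lt(abs(q$value - 1), 1e-6)
  }
  # large-tau tail log-slope -> -alpha (within 2% at tau = 100, sigma2 = 1)
  fp1 <- suppressWarnings(fluct_params(f0 = -1.2, sigma2 = 1))
  xg <- seq(5, 15, by = 0.1)
  lp <- log(fluct_density(xg, T = 100, params = fp1))
  slope <- unname(coef(lm(lp ~ xg))[2])
  expect_equal(-slope, 1.2, tolerance = 0.02)
  # and matches the closed-form asymptote there
  expect_equal(fluct_density(xg, T = 100, params = fp1),
               fluct_density_tail(xg, T = 100, params = fp1),
               tolerance = 0.02)
  # at small tau the tail is much steeper than the asymptote
  lp_small <- log(fluct_density(xg, rescaled = TRUE, tau = 2, alpha = 1.2))
  slope_small <- unname(coef(lm(lp_small ~ xg))[2])
  expect_lt(slope_small, -2)
  expect_error(fluct_density(1, T = 1, params = fluct_params(0.1, 1)),
               "negative")
})

test_that("zero-insertion profile interpolates between its plateaus", {
  rp <- study_relaxation()
  # young limit, top ranks -> p0,-
  expect_equal(zero_insertion_profile(10, 1e-9, rp), 0.07, tolerance = 1e-9)
  # deep ranks -> p0,+
  expect_equal(zero_insertion_profile(1e9, 1e-9, rp), 0.02, tolerance = 1e-9)
  # value at r = r*, t = tau_d: delta_p0/2 * erfc(1/2) + p0,+
  v <- zero_insertion_profile(rp$r_star, rp$tau_d, rp)
  expect_equal(v, 0.025 * erfc(0.5) + 0.02, tolerance = 1e-12)
  expect_equal(v, 0.0319875, tolerance = 1e-6)
  # monotone non-increasing in rank
  rr <- 10^seq(0, 8, length.out = 100)
  expect_true(all(diff(zero_insertion_profile(rr, 20, rp)) <= 0))
  # for r < r*, non-increasing in t
  tt <- seq(0.5, 80, length.out = 100)
  expect_true(all(diff(zero_insertion_profile(100, tt, rp)) <= 0))
})

test_that("early-fraction composition reproduces the rank-space sigmoid exactly", {
  rp <- study_relaxation()
  # consistent fluctuation parameters: tau_d = 1/(alpha*sigma)^2
  alpha <- 1.1
  sigma2 <- 1 / (alpha^2 * rp$tau_d)
  fp <- suppressWarnings(fluct_params(f0 = -alpha * sigma2, sigma2 = sigma2))
  x_min <- 3
  # limits
  expect_equal(early_fraction(40, 1, x_min, fp), 1, tolerance = 1e-9)
  expect_equal(early_fraction(3, 1e9, x_min, fp), 0, tolerance = 1e-6)
  # algebraic identity: P0 = delta_p0 * f_early + p0,+ after the rank map
  r <- 10^seq(0, 7, length.out = 60)
  for (t in c(1, 9.1, 40)) {
    x <- x_min - log(r / rp$r_star) / alpha
    lhs <- rp$delta_p0 * early_fraction(x, t, x_min, fp) + rp$p0_plus
    expect_equal(lhs, zero_insertion_profile(r, t, rp), tolerance = 1e-12)
  }
})

test_that("neutral steady state is the normalized log-series law", {
  C <- 1:2000
  p <- neutral_steady_state(C, b_per_cell = 0.5, d = 1)
  expect_lt(abs(sum(p) - 1), 1e-10)
  # b/d -> 0: all mass at C = 1
  expect_gt(neutral_steady_state(1, 1e-6, 1), 1 - 1e-5)
  expect_error(neutral_steady_state(1, 2, 1), "stationary")
})

test_that("neutral log-series matches long-run occupancy of a simulated neutral chain", {
  # independent oracle: plain Gillespie simulation of the neutral
  # birth-death-immigration chain (constant per-cell birth rate b < d)
  set.seed(42)
  b <- 0.5; d <- 1; theta <- 60
  t <- 0
  pool <- numeric(0)  # clone sizes
  # burn-in 15, then snapshots spaced several turnover times apart so the
  # pooled occupancies are close to independent
  snap_at <- seq(15, 115, by = 2.5)
  k <- 1
  pooled <- integer(0)
  while (t < 115) {
    N <- sum(pool)
    rate <- theta + (b + d) * N
    t <- t + rexp(1, rate)
    while (k <= length(snap_at) && snap_at[k] < t) {
      pooled <- c(pooled, pool[pool > 0])
      k <- k + 1
    }
    u <- runif(1) * rate
    if (u < theta) {
      pool <- c(pool, 1)
    } else {
      i <- sample.int(length(pool), 1, prob = pool)
      pool[i] <- pool[i] + if (u < theta + b * N) 1 else -1
    }
  }
  # chi-squared against the log-series, binning the tail
  cap <- 6
  obs <- tabulate(pmin(pooled, cap), nbins = cap)
  pr <- neutral_steady_state(1:(cap - 1), b, d)
  pr <- c(pr, 1 - sum(pr))
  chi <- suppressWarnings(chisq.test(obs, p = pr))
  expect_gt(chi$p.value, 0.01)
})
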