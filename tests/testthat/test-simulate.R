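# Stochastic simulators: exact Gillespie, mean-field thinning, GBM.

test_that("exact simulation with no clone source stays empty", {
  p <- formation_params(b0 = 100, d = 0.5, theta = 0)
  sim <- simulate_exact(sim_config(p, t_end = 2, record_times = c(1, 2),
                                   seed = 1))
  expect_equal(nrow(sim), 0)
})

test_that("exact simulation reproduces the pure death process", {
  # b0 ~ 0, theta = 0: each seeded clone decays with mean C0 * exp(-d*t)
  p <- formation_params(b0 = 1e-12, d = 0.5, theta = 0)
  cfg <- sim_config(p, t_end = 2, record_times = c(0.5, 1, 2), seed = 3)
  n0 <- 400; c0 <- 40
  sim <- simulate_exact(cfg, init = data.frame(size = rep(c0, n0)))
  for (tk in cfg$record_times) {
    tot <- sum(sim$size[sim$time == tk])
    mu <- n0 * c0 * exp(-p$d * tk)
    sdev <- sqrt(n0 * c0 * exp(-p$d * tk) * (1 - exp(-p$d * tk)))  # binomial
    expect_lt(abs(tot - mu), 4 * sdev + 1)
  }
})

test_that("simulations are reproducible given seed and config", {
  p <- small_formation(theta = 500)
  cfg <- sim_config(p, t_end = 2, record_times = c(1, 2), seed = 99)
  expect_identical(simulate_exact(cfg), simulate_exact(cfg))
  cfgm <- sim_config(p, t_end = 2, record_times = c(1, 2), seed = 99,
                     mode = "meanfield")
  expect_identical(simulate_meanfield(cfgm), simulate_meanfield(cfgm))
  fp <- study_fluct()
  expect_identical(simulate_fluctuating(fp, rep(0, 5), 0:3, seed = 7),
                   simulate_fluctuating(fp, rep(0, 5), 0:3, seed = 7))
})

test_that("config validation rejects bad horizons and modes", {
  p <- small_formation()
  expect_error(sim_config(p, t_end = 0), "positive")
  expect_error(sim_config(p, t_end = -1), "positive")
  expect_error(simulate_exact(sim_config(p, 1, mode = "meanfield")), "exact")
  expect_error(simulate_meanfield(sim_config(p, 1, mode = "exact")),
               "meanfield")
  expect_error(meanfield_clone_replicates(0, 1, p), "positive")
})

test_that("mean-field single-clone growth matches the deterministic law (d = 0)", {
  # pure birth: mean size C0 * (t/ti)^(1/(1+gamma))
  p <- formation_params(b0 = 2000, d = 0, theta = 200)
  m <- meanfield_clone_replicates(0.1, c(1, 2), p, n_reps = 4000, seed = 5)
  for (j in 1:2) {
    th <- clone_growth(c(1, 2)[j], 0.1, p, early_limit = TRUE)
    se <- sd(m[, j]) / sqrt(nrow(m))
    expect_lt(abs(mean(m[, j]) - th), 3.5 * se)
  }
})

test_that("mean-field single-clone sizes are geometric (thinning correctness)", {
  # for d = 0 the clone is a time-inhomogeneous pure birth process started
  # from one cell, so its size is geometric with mean (t/ti)^(1/(1+gamma));
  # an exact distributional oracle for the thinning sampler.
  p <- formation_params(b0 = 2000, d = 0, theta = 200)
  ti <- 0.05; tend <- 0.5
  m <- meanfield_clone_replicates(ti, tend, p, n_reps = 6000, seed = 11)
  mu <- clone_growth(tend, ti, p, early_limit = TRUE)
  pg <- 1 / mu
  cap <- 25
  obs <- tabulate(pmin(m[, 1], cap), nbins = cap)
  pr <- dgeom(0:(cap - 2), prob = pg)
  pr <- c(pr, 1 - sum(pr))
  chi <- suppressWarnings(chisq.test(obs, p = pr))
  expect_gt(chi$p.value, 0.01)
})

test_that("ensemble mean of total mean-field size follows the growth curve", {
  # gamma = 2 keeps the clone-size variance finite so the ensemble mean is
  # well behaved at modest replicate numbers
  p <- formation_params(b0 = 500, d = 0.2, theta = 1000)
  rec <- c(0.5, 1.5, 3)
  tot <- t(sapply(1:40, function(s) {
    sim <- simulate_meanfield(sim_config(p, 3, rec, seed = s,
                                         mode = "meanfield"))
    sapply(rec, function(tk) sum(sim$size[sim$time == tk]))
  }))
  for (j in seq_along(rec)) {
    se <- sd(tot[, j]) / sqrt(nrow(tot))
    expect_lt(abs(mean(tot[, j]) - mean_total_size(rec[j], p)), 3 * se)
  }
})

test_that("mean-field snapshots drop extinct clones and carry dating flags", {
  p <- small_formation(theta = 300)
  cp <- desk_cohort()
  cfg <- sim_config(p, 3, c(1, 3), seed = 2, mode = "meanfield")
  sim <- simulate_meanfield(cfg, p0_fun = function(t) p0_of_time(t, cp))
  expect_true(all(sim$size >= 1))
  expect_type(sim$zero_insertions, "logical")
  expect_true(all(sim$t_recruit > 0))
  expect_true(all(sim$t_recruit <= sim$time))
})

test_that("GBM trajectories have exact moments and Gaussian increments", {
  fp <- study_fluct()
  # sigma2 = 0: deterministic drift
  fp0 <- fluct_params(f0 = -0.05, sigma2 = 0)
  tr0 <- simulate_fluctuating(fp0, c(0, 1), c(0, 2, 4), seed = 1)
  expect_equal(tr0$x, c(0, 1, -0.1, 0.9, -0.2, 0.8), tolerance = 1e-12)
  # moments over 1e4 replicates at t = 0.7
  tr <- simulate_fluctuating(fp, rep(0, 1e4), c(0, 0.3, 0.7), seed = 2)
  xt <- tr$x[tr$time == 0.7]
  expect_lt(abs(mean(xt) - fp$f0 * 0.7),
            4 * sqrt(2 * fp$sigma2 * 0.7 / 1e4))
  expect_equal(var(xt), 2 * fp$sigma2 * 0.7, tolerance = 0.06)
  # distribution matches the Green's function (KS against the stated normal)
  ks <- ks.test(xt, "pnorm", mean = fp$f0 * 0.7,
                sd = sqrt(2 * fp$sigma2 * 0.7))
  expect_gt(ks$p.value, 0.001)
  expect_error(simulate_fluctuating(fluct_params(0, 1), 0, c(0, 1, 0.5)),
               "increasing")
})

test_that("snapshots export as clone tables with a config sidecar", {
  p <- small_formation(theta = 300)
  cfg <- sim_config(p, 2, 2, seed = 4, mode = "meanfield")
  sim <- simulate_meanfield(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_snapshot(sim, path, config = cfg)
  back <- read_clone_table(path)
  expect_equal(back$count, sim$size)
  expect_equal(back$t_recruit, sim$t_recruit, tolerance = 1e-9)
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  expect_equal(meta$seed, 4)
  expect_equal(meta$params$theta, 300)
})
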