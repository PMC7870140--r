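# Longitudinal fluctuation analysis: variance curves, sigma2 estimation,
# rank-origin composition.

test_that("constant trajectories give zero variance at all lags", {
  tr <- tibble::tibble(
    clone_id = rep(1:50, 4),
    time = rep(0:3, each = 50),
    count = rep(1000:1049, 4)
  )
  cv <- logfold_variance_curve(tr, top_n = 50, min_clones = 10)
  expect_equal(cv$variance, rep(0, nrow(cv)), tolerance = 1e-12)
})

test_that("GBM data produce the predicted linear variance curve", {
  fp <- fluct_params(f0 = -0.04, sigma2 = 0.08)
  tp <- seq(0, 2, length.out = 9)
  tr <- generate_longitudinal(fp, 2000, tp, sampling_noise_var = 0, seed = 6)
  cv <- logfold_variance_curve(tr, value = "x", top_n = 2000)
  # variance ~ 2*sigma2*dt within Monte-Carlo error at every lag
  expect_equal(cv$variance, 2 * fp$sigma2 * cv$dt, tolerance = 0.12)
  # linearity: R^2 > 0.9 with >= 6 timepoints and >= 200 clones
  r2 <- summary(lm(variance ~ dt, data = cv))$r.squared
  expect_gt(r2, 0.9)
})

test_that("observation noise shifts the curve up without changing its slope", {
  fp <- fluct_params(f0 = -0.04, sigma2 = 0.08)
  tp <- seq(0, 2, length.out = 9)
  lat <- generate_longitudinal(fp, 3000, tp, sampling_noise_var = 0, seed = 7)
  noisy <- lat
  set.seed(8)
  noisy$x <- noisy$x_latent + rnorm(nrow(noisy), sd = sqrt(0.01))
  cv0 <- logfold_variance_curve(lat, value = "x", top_n = 3000)
  cv1 <- logfold_variance_curve(noisy, value = "x", top_n = 3000)
  shift <- cv1$variance - cv0$variance
  expect_equal(mean(shift), 0.02, tolerance = 0.15)
  s0 <- coef(lm(variance ~ dt, data = cv0))[2]
  s1 <- coef(lm(variance ~ dt, data = cv1))[2]
  expect_equal(unname(s1), unname(s0), tolerance = 0.1)
})

test_that("a common deterministic drift cancels from the variance curve", {
  tp <- seq(0, 2, length.out = 8)
  fp_a <- fluct_params(f0 = 0, sigma2 = 0.05)
  fp_b <- suppressWarnings(fluct_params(f0 = -0.5, sigma2 = 0.05))
  tr_a <- generate_longitudinal(fp_a, 500, tp, 0, seed = 9)
  tr_b <- generate_longitudinal(fp_b, 500, tp, 0, seed = 9)
  cv_a <- logfold_variance_curve(tr_a, value = "x", top_n = 500)
  cv_b <- logfold_variance_curve(tr_b, value = "x", top_n = 500)
  expect_equal(cv_a$variance, cv_b$variance, tolerance = 1e-10)
})

test_that("fluctuation strength estimation inverts exact and synthetic curves", {
  # arithmetic inversion of an exact line v = 0.16*dt + 0.01
  curve <- tibble::tibble(dt = c(0.25, 0.5, 0.75, 1),
                          variance = 0.16 * c(0.25, 0.5, 0.75, 1) + 0.01)
  est <- estimate_fluctuation_strength(curve, n_boot = 50, seed = 1)
  expect_equal(est$sigma2_hat, 0.08, tolerance = 1e-10)
  expect_equal(est$sampling_var_hat, 0.005, tolerance = 1e-10)
  # estimator consistency at 1e4 clones
  fp <- fluct_params(f0 = -0.04, sigma2 = 0.08)
  tr <- generate_longitudinal(fp, 1e4, seq(0, 1, length.out = 8), 0.005,
                              seed = 10)
  cv <- logfold_variance_curve(tr, value = "x", top_n = 1e4)
  est2 <- estimate_fluctuation_strength(cv, n_boot = 200, seed = 2)
  expect_equal(est2$sigma2_hat, 0.08, tolerance = 0.1)
  # pure-noise null: sigma2 ~ 0, intercept ~ 2*sigma_S^2
  fp0 <- fluct_params(f0 = 0, sigma2 = 0)
  tr0 <- generate_longitudinal(fp0, 3000, seq(0, 1, length.out = 6), 0.02,
                               seed = 11)
  cv0 <- logfold_variance_curve(tr0, value = "x", top_n = 3000)
  est0 <- tryCatch(estimate_fluctuation_strength(cv0, n_boot = 50, seed = 3),
                   warning = function(w) suppressWarnings(
                     estimate_fluctuation_strength(cv0, n_boot = 50, seed = 3)))
  expect_lt(est0$sigma2_hat, 0.005)
  expect_equal(est0$sampling_var_hat, 0.02, tolerance = 0.25)
  # tidiers
  td <- tidy(est2)
  expect_equal(td$estimate[td$term == "sigma2"], est2$sigma2_hat)
  expect_true(glance(est2)$n_dt >= 3)
})

test_that("the eligibility filter reports too-small clone sets", {
  tr <- tibble::tibble(clone_id = rep(1:5, 3), time = rep(0:2, each = 5),
                       count = rep(10, 15))
  expect_error(logfold_variance_curve(tr, top_n = 5), "eligible")
})

test_that("rank-origin composition partitions the top clones", {
  # identical repertoires: everything originates from the top bin
  counts <- sort(rpois(200, 50) + 1, decreasing = TRUE) + seq(200, 1)
  tr <- tibble::tibble(clone_id = rep(1:200, 3), time = rep(0:2, each = 200),
                       count = rep(counts, 3))
  comp <- rank_origin_composition(tr, top_n = 100,
                                  origin_bins = c(1, 101, 1001))
  expect_true(all(abs(tapply(comp$fraction, comp$time, sum) - 1) < 1e-12))
  top_frac <- comp$fraction[comp$origin == "1-100"]
  expect_equal(unname(top_frac), rep(1, 2))
  # slow fluctuations: small ND fraction, majority from the top origin bins
  set.seed(12)
  n <- 3000
  x0 <- log(generate_zipf_sample(1.2, n, seed = 13)$count) +
    runif(n) * 1e-3 + 3
  fp <- fluct_params(f0 = 0, sigma2 = 0.08)
  lat <- simulate_fluctuating(fp, x0, c(0, 1), seed = 14)
  wide <- tidyr::pivot_wider(lat, names_from = "time", values_from = "x")
  f1 <- exp(wide$`0`) / sum(exp(wide$`0`))
  f2 <- exp(wide$`1`) / sum(exp(wide$`1`))
  tr2 <- tibble::tibble(
    clone_id = rep(wide$clone_id, 2),
    time = rep(c(0, 1), each = n),
    count = c(rpois(n, 3e4 * f1), rpois(n, 3e4 * f2))
  )
  comp2 <- rank_origin_composition(tr2, top_n = 200,
                                   origin_bins = c(1, 201, 1001))
  nd <- comp2$fraction[comp2$origin == "ND"]
  expect_lt(nd, 0.1)
  expect_gt(comp2$fraction[comp2$origin == "1-200"], 0.6)
})
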