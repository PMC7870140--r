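# Shared fixtures: small parameter sets used across test files.

fig_formation <- function() formation_params(b0 = 1e7, d = 0.2, theta = 1e6)

# small repertoire with the same gamma = 0.1
small_formation <- function(theta = 1e4) {
  formation_params(b0 = theta / 0.1, d = 0.2, theta = theta)
}

# alpha = 1.2 deliberately sits outside the stability band, so silence the
# (tested elsewhere) warning in fixtures
study_fluct <- function() {
  suppressWarnings(fluct_params(f0 = -0.096, sigma2 = 0.08))
}

study_relaxation <- function() {
  relaxation_params(r_star = 1.2e4, tau_d = 9.1, p0_minus = 0.07,
                    p0_plus = 0.02)
}

desk_cohort <- function() {
  cohort_params(theta = 1e4, n_sample = 5e4)
}

# exact enrichment table generated from the sigmoid itself (noiseless)
sigmoid_table <- function(params, se = 1e-3,
                          ranks = exp(seq(log(250), log(2e4), length.out = 12)),
                          ages = c(5, 15, 25, 45, 65)) {
  grid <- expand.grid(rank_mid = ranks, age_mid = ages)
  tibble::tibble(
    age_mid = grid$age_mid,
    rank_mid = grid$rank_mid,
    fraction_zero = zero_insertion_profile(grid$rank_mid, grid$age_mid, params),
    se = se,
    n_clones = 1000L
  )
}
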