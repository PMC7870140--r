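#' Parameters of the repertoire-formation model
#'
#' Bundles the rates of the competitive birth-death-immigration model of
#' repertoire formation: cells of every clone proliferate at a shared total
#' rate `b0` partitioned in proportion to clone size (per-cell rate `b0/N`),
#' die at per-cell rate `d`, and new clones of `C0` cells are recruited at
#' rate `theta`. The dimensionless recruitment-to-proliferation ratio
#' `gamma = theta * C0 / b0` controls the formation-phase clone-size exponent
#' `alpha = 1 + gamma` and is derived, never stored independently.
#'
#' @param b0 Total proliferation rate (cells/year), positive.
#' @param d Per-cell death rate (1/year), non-negative (`d = 0` is accepted as
#'   the no-turnover limit used in analytic checks).
#' @param theta Clone recruitment rate (clones/year), non-negative.
#' @param C0 Recruitment size (cells), positive integer. Default 1.
#'
#' @return An object of class `formation_params`: a list with elements `b0`,
#'   `d`, `theta`, `C0` and the derived `gamma`.
#' @examples
#' formation_params(b0 = 1e7, d = 0.2, theta = 1e6)
#' @export
formation_params <- function(b0, d = 0.2, theta, C0 = 1L) {
  stopifnot(is.numeric(b0), length(b0) == 1, b0 > 0, is.finite(b0))
  stopifnot(is.numeric(d), length(d) == 1, d >= 0, is.finite(d))
  stopifnot(is.numeric(theta), length(theta) == 1, theta >= 0, is.finite(theta))
  stopifnot(is.numeric(C0), length(C0) == 1, C0 >= 1, C0 == round(C0))
  structure(
    list(b0 = b0, d = d, theta = theta, C0 = as.integer(C0),
         gamma = theta * C0 / b0),
    class = "formation_params"
  )
}

#' @export
print.formation_params <- function(x, ...) {
  cat("Repertoire formation parameters\n")
  cat(sprintf("  b0 = %g cells/yr, d = %g /yr, theta = %g clones/yr, C0 = %d\n",
              x$b0, x$d, x$theta, x$C0))
  cat(sprintf("  gamma = theta*C0/b0 = %g  (tail exponent alpha = %g)\n",
              x$gamma, 1 + x$gamma))
  invisible(x)
}

#' Parameters of the fluctuating clonal selection model
#'
#' Parameters of the geometric Brownian motion description of adult clone-size
#' dynamics: the log clone size performs Brownian motion with drift `f0`
#' (mean log-growth rate, typically negative so clonal decay balances
#' recruitment) and diffusion constant `sigma2` (growth-rate fluctuation
#' strength; increments over time `dt` have variance `2 * sigma2 * dt`).
#' The derived steady-state tail exponent is `alpha = -f0 / sigma2`, and the
#' derived hierarchy-reordering timescale is `tau_d = 1 / (alpha * sigma)^2`.
#'
#' A warning (not an error) is emitted when `-f0 >= sigma2`: in that regime
#' the expected linear-scale clone size shrinks deterministically, violating
#' the stability condition that large clones should not deterministically
#' lose repertoire share.
#'
#' @param f0 Mean log-growth rate (1/year).
#' @param sigma2 Growth-rate fluctuation strength (1/year), positive.
#'
#' @return An object of class `fluct_params` with elements `f0`, `sigma2` and
#'   derived `alpha` and `tau_d` (`tau_d` is `NA` when `f0 >= 0`).
#' @examples
#' fluct_params(f0 = -0.096, sigma2 = 0.08)
#' @export
fluct_params <- function(f0, sigma2) {
  stopifnot(is.numeric(f0), length(f0) == 1, is.finite(f0))
  stopifnot(is.numeric(sigma2), length(sigma2) == 1, is.finite(sigma2),
            sigma2 >= 0)
  alpha <- if (sigma2 > 0) -f0 / sigma2 else NA_real_
  if (is.finite(alpha) && -f0 >= sigma2 && f0 < 0) {
    warning("-f0 >= sigma2: expected linear-scale clone size decays ",
            "deterministically (stability condition violated)", call. = FALSE)
  }
  tau_d <- if (is.finite(alpha) && alpha > 0) 1 / (alpha^2 * sigma2) else NA_real_
  structure(list(f0 = f0, sigma2 = sigma2, alpha = alpha, tau_d = tau_d),
            class = "fluct_params")
}

#' @export
print.fluct_params <- function(x, ...) {
  cat("Fluctuating selection parameters (geometric Brownian motion)\n")
  cat(sprintf("  f0 = %g /yr, sigma2 = %g /yr\n", x$f0, x$sigma2))
  cat(sprintf("  alpha = -f0/sigma2 = %g, tau_d = %g yr\n", x$alpha, x$tau_d))
  invisible(x)
}

#' Parameters of the zero-insertion relaxation sigmoid
#'
#' Parameters of the sigmoidal profile describing how the fraction of
#' zero-insertion clones depends on clone-size rank and age: `r_star` is the
#' rank scale separating clones founded during the early, pre-TdT expansion
#' wave from later recruits; `tau_d` is the timescale over which fluctuating
#' selection reorders the clone-size hierarchy; `p0_minus` and `p0_plus` are
#' the zero-insertion probabilities of early- and late-produced clones.
#'
#' @param r_star Rank scale (clones), `>= 1`.
#' @param tau_d Hierarchy-reordering timescale (years), positive.
#' @param p0_minus Zero-insertion probability early in life, in `[0, 1]`.
#' @param p0_plus Adult zero-insertion probability, in `[0, p0_minus]`.
#'
#' @return An object of class `relaxation_params` with the four parameters and
#'   the derived `delta_p0 = p0_minus - p0_plus`.
#' @examples
#' relaxation_params(r_star = 1.2e4, tau_d = 9.1, p0_minus = 0.07, p0_plus = 0.02)
#' @export
relaxation_params <- function(r_star, tau_d, p0_minus, p0_plus) {
  stopifnot(is.numeric(r_star), length(r_star) == 1, r_star >= 1)
  stopifnot(is.numeric(tau_d), length(tau_d) == 1, tau_d > 0)
  stopifnot(is.numeric(p0_minus), length(p0_minus) == 1,
            p0_minus >= 0, p0_minus <= 1)
  stopifnot(is.numeric(p0_plus), length(p0_plus) == 1,
            p0_plus >= 0, p0_plus <= p0_minus)
  structure(
    list(r_star = r_star, tau_d = tau_d, p0_minus = p0_minus,
         p0_plus = p0_plus, delta_p0 = p0_minus - p0_plus),
    class = "relaxation_params"
  )
}

#' Cytokine competition parameters
#'
#' Parameters of the mechanistic competition model in which proliferation is
#' proportional to the concentration of a stimulatory cytokine produced at
#' rate `p`, degraded at basal rate `q`, and consumed by T cells with mass
#' action rate constant `k`.
#'
#' @param p Cytokine production rate, positive.
#' @param q Basal degradation rate, positive.
#' @param k Consumption rate constant per T cell, positive.
#'
#' @return An object of class `cytokine_params`.
#' @export
cytokine_params <- function(p, q, k) {
  stopifnot(p > 0, q > 0, k > 0)
  structure(list(p = p, q = q, k = k), class = "cytokine_params")
}

#' Parameters of the synthetic cohort generator
#'
#' Defaults are the simulated-cohort study conditions: clone-size fluctuation
#' strength `sigma2 = 0.08`/yr, death rate `d = 0.2`/yr, recruitment-to-
#' proliferation ratio `gamma = 0.1`, recruitment rate `theta = 1e5`/yr,
#' early-life zero-insertion fraction `p0_minus = 0.07`, adult fraction
#' `p0_plus = 0.02`, recombination-statistics switch time `t_dagger = 0.05` yr,
#' and a simulated sequencing depth of `n_sample = 5e5` reads per individual
#' drawn from individuals aged uniformly on `[0, 80]` years.
#'
#' @param sigma2 Clone-size fluctuation strength (1/year).
#' @param d Death rate (1/year).
#' @param gamma Recruitment-to-proliferation ratio (dimensionless).
#' @param theta Recruitment rate (clones/year).
#' @param p0_minus Zero-insertion fraction early in life.
#' @param p0_plus Adult zero-insertion fraction.
#' @param t_dagger Time of the recombination-statistics switch (years).
#' @param n_sample Sequencing depth (reads per individual).
#' @param age_range Two-element numeric, age range in years.
#'
#' @return An object of class `cohort_params`.
#' @examples
#' cohort_params()                      # study defaults
#' cohort_params(theta = 1e4, n_sample = 5e4)  # desk-scale variant
#' @export
cohort_params <- function(sigma2 = 0.08, d = 0.2, gamma = 0.1, theta = 1e5,
                          p0_minus = 0.07, p0_plus = 0.02, t_dagger = 0.05,
                          n_sample = 5e5, age_range = c(0, 80)) {
  stopifnot(sigma2 >= 0, d >= 0, gamma > 0, theta > 0, t_dagger > 0,
            n_sample >= 0)
  stopifnot(p0_minus >= 0, p0_minus <= 1, p0_plus >= 0, p0_plus <= p0_minus)
  stopifnot(length(age_range) == 2, age_range[1] >= 0,
            age_range[2] > age_range[1])
  structure(
    list(sigma2 = sigma2, d = d, gamma = gamma, theta = theta,
         p0_minus = p0_minus, p0_plus = p0_plus, t_dagger = t_dagger,
         n_sample = n_sample, age_range = as.numeric(age_range)),
    class = "cohort_params"
  )
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("Synthetic cohort parameters\n")
  cat(sprintf("  sigma2 = %g /yr, d = %g /yr, gamma = %g, theta = %g clones/yr\n",
              x$sigma2, x$d, x$gamma, x$theta))
  cat(sprintf("  p0- = %g, p0+ = %g, t_dagger = %g yr\n",
              x$p0_minus, x$p0_plus, x$t_dagger))
  cat(sprintf("  n_sample = %g reads, ages on [%g, %g] yr\n",
              x$n_sample, x$age_range[1], x$age_range[2]))
  invisible(x)
}

#' Simulation configuration
#'
#' Plumbing object pairing formation-model parameters with a simulation
#' horizon, recording times and a seed.
#'
#' @param params A [formation_params()] object.
#' @param t_end Simulation end time (years), positive.
#' @param record_times Strictly increasing times in `[0, t_end]` at which
#'   snapshots are recorded. Defaults to `t_end` only.
#' @param seed Integer RNG seed or `NULL` to use the current RNG state.
#' @param mode `"exact"` or `"meanfield"`.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(params, t_end, record_times = t_end, seed = NULL,
                       mode = c("exact", "meanfield")) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "formation_params"))
  if (!is.numeric(t_end) || length(t_end) != 1 || t_end <= 0)
    stop("t_end must be a single positive number", call. = FALSE)
  record_times <- as.numeric(record_times)
  stopifnot(length(record_times) >= 1, all(record_times >= 0),
            all(record_times <= t_end), !is.unsorted(record_times, strictly = TRUE))
  if (!is.null(seed)) stopifnot(is.numeric(seed), length(seed) == 1)
  structure(list(params = params, t_end = t_end, record_times = record_times,
                 seed = seed, mode = mode),
            class = "sim_config")
}
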