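# Closed-form theory of repertoire formation and fluctuating clonal selection.
# All functions are pure and vectorized over their first argument(s).

#' Complementary error function
#'
#' `erfc(x) = 2/sqrt(pi) * integral_x^Inf exp(-t^2) dt`, evaluated through the
#' normal tail probability so that large arguments underflow gracefully.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length.
#' @export
erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

#' Mean total repertoire size
#'
#' Deterministic (continuum) solution for the total number of T cells under
#' competitive homeostasis: `N(t) = (b0 + theta*C0) * (1 - exp(-d*t)) / d`,
#' growing linearly at first and saturating at `(b0 + theta*C0)/d` on the
#' cellular turnover timescale `1/d`. At `d = 0` the linear-growth limit
#' `(b0 + theta*C0) * t` is returned.
#'
#' @param t Time (years), non-negative; vectorized.
#' @param params A [formation_params()] object.
#' @return Numeric vector `N(t)` (cells).
#' @examples
#' p <- formation_params(b0 = 1e7, d = 0.2, theta = 1e6)
#' mean_total_size(c(0, 1, 5, 50), p)
#' @export
mean_total_size <- function(t, params) {
  stopifnot(inherits(params, "formation_params"), all(t >= 0))
  influx <- params$b0 + params$theta * params$C0
  if (params$d == 0) return(influx * t)
  influx * (-expm1(-params$d * t)) / params$d
}

#' Deterministic clonal growth law
#'
#' Size at time `t` of a clone recruited at `t_recruit` under the continuum
#' description of repertoire formation:
#' `C(t) = C0 * ((exp(d*t) - 1) / (exp(d*t_recruit) - 1))^(1/(1+gamma)) *
#' exp(-d*(t - t_recruit))`. For times short compared to `1/d` this reduces to
#' the subexponential power-law growth `C0 * (t/t_recruit)^(1/(1+gamma))`
#' (`early_limit = TRUE`): clones recruited earlier into a small repertoire
#' expand more before competition shuts growth off.
#'
#' @param t Observation time (years); vectorized jointly with `t_recruit`.
#' @param t_recruit Recruitment time (years), strictly positive and `<= t`.
#' @param params A [formation_params()] object.
#' @param early_limit If `TRUE`, use the small-time power-law form.
#' @return Numeric vector of clone sizes (cells, real-valued).
#' @examples
#' p <- formation_params(b0 = 1e7, d = 0.2, theta = 1e6)
#' clone_growth(1, 0.1, p, early_limit = TRUE)  # 10^(1/1.1)
#' @export
clone_growth <- function(t, t_recruit, params, early_limit = FALSE) {
  stopifnot(inherits(params, "formation_params"))
  if (any(t_recruit <= 0))
    stop("t_recruit must be strictly positive (the growth law diverges at 0)",
         call. = FALSE)
  if (any(t < t_recruit)) stop("need t >= t_recruit", call. = FALSE)
  ex <- 1 / (1 + params$gamma)
  if (early_limit || params$d == 0) {
    params$C0 * (t / t_recruit)^ex
  } else {
    d <- params$d
    params$C0 * (expm1(d * t) / expm1(d * t_recruit))^ex * exp(-d * (t - t_recruit))
  }
}

#' Clone-size rank exponent during repertoire formation
#'
#' The rank of the largest clones scales with size as `rank ~ C^(-alpha)` with
#' `alpha = 1 + gamma`, where `gamma` is the recruitment-to-proliferation
#' ratio. (The exponent of the size *density* `P(C) ~ C^(-2-gamma)` differs by
#' one, as the rank distribution is a complementary cumulative.)
#'
#' @param gamma Recruitment-to-proliferation ratio, non-negative; vectorized.
#' @return `1 + gamma`.
#' @export
formation_exponent <- function(gamma) {
  stopifnot(all(gamma >= 0))
  1 + gamma
}

#' Crossover time to effectively neutral dynamics
#'
#' Time `t_star = log(1 + 1/gamma) / d` at which the per-cell proliferation
#' rate `b0/N(t)` falls below the death rate `d`, after which large clones
#' drift toward extinction and the model approaches neutral birth-death
#' dynamics.
#'
#' @param params A [formation_params()] object with `gamma > 0` and `d > 0`.
#' @return Crossover time in years.
#' @export
crossover_time <- function(params) {
  stopifnot(inherits(params, "formation_params"))
  if (params$gamma <= 0) stop("gamma must be positive", call. = FALSE)
  if (params$d <= 0) stop("d must be positive", call. = FALSE)
  log1p(1 / params$gamma) / params$d
}

#' Quasi-steady-state cytokine concentration
#'
#' `S = p / (q + k*N)`: with production at rate `p`, basal degradation `q`,
#' and consumption by `N` T cells at mass-action rate `k`. When consumption
#' dominates (`k*N >> q`), `S` is inversely proportional to `N`, motivating
#' the `b0/N` competition function of the formation model.
#'
#' @param N Total T cell number, non-negative; vectorized.
#' @param params A [cytokine_params()] object.
#' @return Cytokine concentration.
#' @export
cytokine_quasi_steady <- function(N, params) {
  stopifnot(inherits(params, "cytokine_params"), all(N >= 0))
  params$p / (params$q + params$k * N)
}

#' Green's function of the fluctuating selection dynamics
#'
#' Transition density of the log clone size under geometric Brownian motion:
#' a normal density in `x` with mean `y + f0*t` and variance `2*sigma2*t`.
#'
#' @param x Log clone size at which the density is evaluated; vectorized.
#' @param y Initial log clone size.
#' @param t Elapsed time (years), strictly positive.
#' @param params A [fluct_params()] object.
#' @return Density values.
#' @export
gbm_green <- function(x, y, t, params) {
  stopifnot(inherits(params, "fluct_params"))
  if (any(t <= 0)) stop("t must be strictly positive", call. = FALSE)
  stats::dnorm(x, mean = y + params$f0 * t, sd = sqrt(2 * params$sigma2 * t))
}

# Shared kernel for the finite-time log-size density of the fluctuating
# fitness model with uniformly distributed clonal ages on [0, T], in the
# rescaled variables tau = T*sigma2, alpha = -f0/sigma2.  Derived by
# integrating the Green's function over clonal age; verified against
# quadrature.  Heaviside convention theta(0) = 1: x = 0 uses the x >= 0
# branch (the two branches agree at x = 0, so this is purely a convention).
log_erfc <- function(z) {
  log(2) + stats::pnorm(z * sqrt(2), lower.tail = FALSE, log.p = TRUE)
}

fluct_density_kernel <- function(x, tau, alpha) {
  stopifnot(all(tau > 0), all(alpha > 0))
  a <- abs(x)
  s <- sqrt(4 * tau)
  le_a <- log_erfc((a - alpha * tau) / s)  # argument -> -Inf at large tau
  le_b <- log_erfc((a + alpha * tau) / s)  # argument -> +Inf at large tau
  pref <- 1 / (2 * alpha * tau)
  # exponential-times-erfc products evaluated in log space so extreme |x|
  # underflows to 0 instead of producing Inf * 0
  ifelse(x >= 0,
         pref * (exp(-alpha * x + le_a) - exp(le_b)),
         pref * (exp(le_a) - exp(-alpha * x + le_b)))
}

#' Finite-time clone-size density of the fluctuating fitness model
#'
#' Density of log clone sizes `x = log(C/C0)` at age `T` when clones are
#' recruited at a constant rate (uniform clonal ages) and each evolves by
#' geometric Brownian motion with drift `f0 < 0` and fluctuation strength
#' `sigma2`. In rescaled form (`rescaled = TRUE`) the density depends only on
#' the effective age `tau = T * sigma2` and the exponent `alpha = -f0/sigma2`.
#' For large `T` and `x > 0` it approaches `exp(f0*x/sigma2) / (-f0*T/sigma2
#' * sigma2)`, i.e. a power-law tail `P(C) ~ C^-(1+alpha)`; at small effective
#' ages the tail is much steeper than this steady-state asymptote, which is
#' why steady-state scaling is approached slowly when fluctuations are weak.
#'
#' @param x Log clone size; vectorized.
#' @param T Age (years); required unless `rescaled = TRUE`.
#' @param params A [fluct_params()] object; required unless `rescaled = TRUE`.
#' @param rescaled If `TRUE`, evaluate in rescaled variables and supply `tau`
#'   and `alpha` instead of `T` and `params`.
#' @param tau Effective age `T * sigma2` (rescaled mode).
#' @param alpha Tail exponent `-f0/sigma2` (rescaled mode).
#' @return Density values (normalized over `x` on the real line).
#' @examples
#' fp <- fluct_params(f0 = -0.096, sigma2 = 0.08)
#' fluct_density(c(-1, 0, 2), T = 30, params = fp)
#' fluct_density(c(5, 10), rescaled = TRUE, tau = 100, alpha = 1.2)
#' @export
fluct_density <- function(x, T = NULL, params = NULL, rescaled = FALSE,
                          tau = NULL, alpha = NULL) {
  if (rescaled) {
    stopifnot(!is.null(tau), !is.null(alpha))
    return(fluct_density_kernel(x, tau, alpha))
  }
  stopifnot(!is.null(T), inherits(params, "fluct_params"))
  if (params$f0 >= 0)
    stop("f0 must be negative (no steady state otherwise)", call. = FALSE)
  if (any(T <= 0)) stop("T must be positive", call. = FALSE)
  fluct_density_kernel(x, T * params$sigma2, params$alpha)
}

#' Large-age power-law tail of the fluctuating fitness model
#'
#' The `T -> Inf`, `x > 0` asymptote of [fluct_density()]:
#' `exp(-alpha*x) / (alpha*tau)` in rescaled variables, i.e. the steady-state
#' power law `P(C) ~ C^-(1+alpha)`. Requires `f0 < 0`.
#'
#' @inheritParams fluct_density
#' @return Tail density values.
#' @export
fluct_density_tail <- function(x, T = NULL, params = NULL, rescaled = FALSE,
                               tau = NULL, alpha = NULL) {
  if (!rescaled) {
    stopifnot(!is.null(T), inherits(params, "fluct_params"))
    if (params$f0 >= 0)
      stop("f0 must be negative (no steady state otherwise)", call. = FALSE)
    tau <- T * params$sigma2
    alpha <- params$alpha
  }
  stopifnot(all(x > 0), all(tau > 0), all(alpha > 0))
  exp(-alpha * x) / (alpha * tau)
}

#' Zero-insertion probability as a function of rank and age
#'
#' Sigmoidal relaxation profile for the probability that a clone of size rank
#' `r` at age `t` has zero inserted nucleotides at both VDJ junctions:
#' \deqn{P_0(r, t) = \frac{\Delta p_0}{2}\,
#'   \mathrm{erfc}\!\left(\frac{\log(r/r^\star) + t/\tau_d}
#'   {2\sqrt{t/\tau_d}}\right) + p_{0,+},}
#' where \eqn{\Delta p_0 = p_{0,-} - p_{0,+}}. It interpolates between the
#' early-life plateau `p0_minus` (top ranks, young ages) and the adult plateau
#' `p0_plus` (deep ranks or old ages), with the transition rank `r_star`
#' drifting and blurring diffusively on the timescale `tau_d`.
#'
#' @param r Clone-size rank, `>= 1`; vectorized.
#' @param t Age (years), strictly positive; vectorized.
#' @param params A [relaxation_params()] object.
#' @return Probabilities in `[p0_plus, p0_minus]`.
#' @examples
#' rp <- relaxation_params(1.2e4, 9.1, 0.07, 0.02)
#' zero_insertion_profile(r = c(10, 1e4, 1e6), t = 40, params = rp)
#' @export
zero_insertion_profile <- function(r, t, params) {
  stopifnot(inherits(params, "relaxation_params"), all(r >= 1), all(t > 0))
  u <- (log(r / params$r_star) + t / params$tau_d) / (2 * sqrt(t / params$tau_d))
  params$delta_p0 / 2 * erfc(u) + params$p0_plus
}

#' Fraction of clones of a given size that are early-founded
#'
#' Under fluctuating selection acting on an established power-law hierarchy in
#' which all clones above log-size `x_min` were founded early, the fraction of
#' clones of log size `x` at time `t` descending from that early set is
#' `f_early(x, t) = 1/2 * erfc((x_min - x + alpha*sigma2*t) /
#' sqrt(4*sigma2*t))` (drift fixed to `f0 = -alpha*sigma2` so the size
#' distribution is stationary). Composed with the rank map
#' `x_min - x = log(r/r_star)/alpha` this reproduces
#' [zero_insertion_profile()] exactly.
#'
#' @param x Log clone size; vectorized.
#' @param t Time since the hierarchy was established (years), positive.
#' @param x_min Log-size threshold above which clones are early-founded.
#' @param params A [fluct_params()] object (uses `sigma2` and `alpha`).
#' @return Fractions in `[0, 1]`.
#' @export
early_fraction <- function(x, t, x_min, params) {
  stopifnot(inherits(params, "fluct_params"), all(t > 0))
  s2 <- params$sigma2
  0.5 * erfc((x_min - x + params$alpha * s2 * t) / sqrt(4 * s2 * t))
}

#' Neutral steady-state clone-size distribution
#'
#' Stationary clone-size law of the neutral birth-death-immigration model with
#' recruitment size 1 and constant per-cell birth rate `b < d`: the
#' logarithmic series distribution `P(C) = (b/d)^C / (C * (-log(1 - b/d)))`
#' for integer `C >= 1`. This is the standard null model accounting only for
#' demographic stochasticity; its short tail is what the repertoire-formation
#' mechanism is contrasted against. The closed form is validated against
#' long-run Monte-Carlo occupancy of the neutral chain in the test suite.
#'
#' @param C Integer clone sizes `>= 1`; vectorized.
#' @param b_per_cell Per-cell birth rate, `0 < b_per_cell < d`.
#' @param d Per-cell death rate.
#' @param C0 Recruitment size; only `C0 = 1` is supported.
#' @return Probabilities summing to 1 over `C >= 1`.
#' @export
neutral_steady_state <- function(C, b_per_cell, d, C0 = 1) {
  if (C0 != 1) stop("only C0 = 1 is supported", call. = FALSE)
  if (b_per_cell <= 0 || b_per_cell >= d)
    stop("need 0 < b_per_cell < d for a stationary distribution", call. = FALSE)
  stopifnot(all(C >= 1), all(C == round(C)))
  r <- b_per_cell / d
  r^C / (C * (-log1p(-r)))
}
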