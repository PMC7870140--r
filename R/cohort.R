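# Synthetic-cohort generation: direct sampling of clone sizes at a given age
# under early deterministic expansion plus fluctuating clonal selection, with
# zero-insertion clone dating; synthetic longitudinal trajectories; pure
# discrete power-law samples for estimator validation.

#' Zero-insertion probability of newly recruited clones
#'
#' Fraction of zero-insertion clones in the naive pool at time `t`: the
#' early value `p0_minus` before TdT expression switches on at `t_dagger`,
#' and afterwards the dilution mixture
#' `p0_minus * (t_dagger / t) + p0_plus * (1 - t_dagger / t)`, where
#' `t_dagger / t` is the fraction of naive clones produced before the switch.
#'
#' @param t Recruitment time (years), non-negative; vectorized.
#' @param params A [cohort_params()] object.
#' @return Probabilities in `[p0_plus, p0_minus]`.
#' @examples
#' p0_of_time(c(0.01, 0.1, 80), cohort_params())
#' @export
p0_of_time <- function(t, params) {
  stopifnot(inherits(params, "cohort_params"), all(t >= 0))
  w <- ifelse(t < params$t_dagger, 1, params$t_dagger / t)
  params$p0_minus * w + params$p0_plus * (1 - w)
}

#' Sample one synthetic individual
#'
#' Direct sampling of the sequenced repertoire of an individual of age `T`:
#' the number of clones is `round(theta * T)`; recruitment times are uniform
#' on `(0, T)`; each clone is flagged zero-insertion with probability
#' [p0_of_time()] at its recruitment time; its latent size is log-normal with
#' mean log-size
#' `-d*(T - t_i) + log((exp(d*T) - 1)/(exp(d*t_i) - 1))/(1 + gamma)
#'  - sigma2*(T - t_i)`
#' and log-variance `2*sigma2*(T - t_i)` (deterministic early growth plus
#' geometric Brownian fluctuations; the `-sigma2*(T - t_i)` term keeps the
#' expected linear-scale size on the deterministic growth law); and sampled
#' read counts are Poisson with depth `n_sample`, dropping unseen clones.
#'
#' @param params A [cohort_params()] object.
#' @param age Age `T` of the individual (years), positive.
#' @param seed Optional integer seed.
#' @param individual_id Identifier stored in the output.
#' @return A tibble with columns `individual_id`, `age`, `clone_id`,
#'   `t_recruit`, `zero_insertions`, `size` (latent cells) and `count`
#'   (sampled reads, `>= 1`).
#' @examples
#' cp <- cohort_params(theta = 100, n_sample = 1000)
#' sample_individual(cp, age = 30, seed = 1)
#' @export
sample_individual <- function(params, age, seed = NULL, individual_id = 1L) {
  stopifnot(inherits(params, "cohort_params"), age > 0)
  M <- round(params$theta * age)
  empty <- tibble::tibble(
    individual_id = integer(0), age = numeric(0), clone_id = integer(0),
    t_recruit = numeric(0), zero_insertions = logical(0),
    size = numeric(0), count = integer(0))
  if (M < 1) {
    warning("theta * age < 1: empty individual", call. = FALSE)
    return(empty)
  }
  with_optional_seed(seed, {
    ti <- stats::runif(M, 0, age)
    zero <- stats::runif(M) < p0_of_time(ti, params)
    dt <- age - ti
    g <- 1 / (1 + params$gamma)
    mu_det <- if (params$d > 0) {
      -params$d * dt + g * (log(expm1(params$d * age) / expm1(params$d * ti)))
    } else {
      g * log(age / ti)
    }
    mu <- mu_det - params$sigma2 * dt
    x <- stats::rnorm(M, mean = mu, sd = sqrt(2 * params$sigma2 * dt))
    size <- exp(x)
    count <- stats::rpois(M, params$n_sample * size / sum(size))
    keep <- which(count > 0)
    tibble::tibble(
      individual_id = individual_id, age = age, clone_id = keep,
      t_recruit = ti[keep], zero_insertions = zero[keep],
      size = size[keep], count = count[keep])
  })
}

#' Sample a synthetic cohort
#'
#' Draws `n_individuals` ages uniformly from `params$age_range` and generates
#' each individual with [sample_individual()] under a per-individual child
#' seed derived from `seed`, so individuals are reproducible independent of
#' evaluation order.
#'
#' @param params A [cohort_params()] object.
#' @param n_individuals Number of individuals, `>= 1`.
#' @param seed Optional integer root seed.
#' @return A tibble (row-bound individuals; see [sample_individual()]).
#' @export
sample_cohort <- function(params, n_individuals, seed = NULL) {
  stopifnot(inherits(params, "cohort_params"), n_individuals >= 1)
  setup <- with_optional_seed(seed, {
    list(ages = stats::runif(n_individuals, params$age_range[1],
                             params$age_range[2]),
         seeds = sample.int(.Machine$integer.max - 1L, n_individuals))
  })
  purrr::map_dfr(seq_len(n_individuals), function(i) {
    sample_individual(params, setup$ages[i], seed = setup$seeds[i],
                      individual_id = i)
  })
}

#' Synthetic longitudinal clone-size trajectories
#'
#' Latent log clone sizes follow geometric Brownian motion
#' ([simulate_fluctuating()]); observed log sizes add independent measurement
#' noise of variance `sampling_noise_var` at every timepoint, emulating
#' sample-to-sample variability. A regression of the variance of observed
#' log-foldchanges on time difference then has slope `2*sigma2` and intercept
#' `2*sampling_noise_var`.
#'
#' @param params A [fluct_params()] object.
#' @param n_clones Number of clones.
#' @param timepoints Strictly increasing observation times (years), `>= 3`.
#' @param sampling_noise_var Variance of the additive observation noise on
#'   log sizes, `>= 0`.
#' @param x0 Initial log sizes (recycled to `n_clones`). Default 0.
#' @param seed Optional integer seed.
#' @return A tibble with columns `clone_id`, `time`, `x_latent`, `x` (the
#'   observed log size).
#' @examples
#' fp <- fluct_params(f0 = 0, sigma2 = 0.08)
#' generate_longitudinal(fp, 10, seq(0, 1, length.out = 8), 0.005, seed = 1)
#' @export
generate_longitudinal <- function(params, n_clones, timepoints,
                                  sampling_noise_var = 0, x0 = 0,
                                  seed = NULL) {
  stopifnot(inherits(params, "fluct_params"), n_clones >= 1,
            sampling_noise_var >= 0)
  timepoints <- as.numeric(timepoints)
  if (length(timepoints) < 3)
    stop("need at least 3 timepoints", call. = FALSE)
  x0 <- rep_len(x0, n_clones)
  with_optional_seed(seed, {
    traj <- simulate_fluctuating(params, x0, timepoints)
    traj$x_latent <- traj$x
    traj$x <- traj$x_latent +
      stats::rnorm(nrow(traj), sd = sqrt(sampling_noise_var))
    traj[, c("clone_id", "time", "x_latent", "x")]
  })
}

#' Sample from the discrete power-law (zeta) distribution
#'
#' Independent draws of integer clone sizes `C >= 1` with
#' `P(C = k) = k^-(1+alpha) / zeta(1+alpha, 1)`, i.e. rank exponent `alpha`
#' and density exponent `1 + alpha`. Sampling inverts the exact CDF: a
#' precomputed table covers the bulk, and the rare draws beyond it are
#' resolved by bisection on the Hurwitz-zeta tail, so the draw is exact at
#' all sizes.
#'
#' @param alpha Rank exponent, positive.
#' @param n_clones Number of draws.
#' @param seed Optional integer seed.
#' @param table_max Size covered by the CDF table (tail handled exactly
#'   beyond it).
#' @return A tibble with columns `clone_id` and `count`.
#' @examples
#' generate_zipf_sample(1.17, 100, seed = 1)
#' @export
generate_zipf_sample <- function(alpha, n_clones, seed = NULL,
                                 table_max = 1e5) {
  stopifnot(alpha > 0, n_clones >= 1)
  s <- 1 + alpha
  z1 <- hurwitz_zeta(s, 1)
  k <- seq_len(table_max)
  cdf <- cumsum(k^(-s)) / z1
  u <- with_optional_seed(seed, stats::runif(n_clones))
  counts <- findInterval(u, cdf) + 1  # smallest k with cdf[k] >= u
  over <- which(counts > table_max)
  if (length(over) > 0) {
    # exact tail inversion: smallest k with P(C <= k) >= u, i.e.
    # zeta(s, k+1)/zeta(s,1) <= 1 - u; bisect on k.
    tail_target <- (1 - u[over]) * z1
    counts[over] <- vapply(tail_target, function(tt) {
      lo <- table_max  # P(C <= lo) < u
      hi <- table_max * 2
      while (hurwitz_zeta(s, hi + 1) > tt) hi <- hi * 4
      while (hi - lo > 1) {
        mid <- floor((lo + hi) / 2)
        if (hurwitz_zeta(s, mid + 1) <= tt) hi <- mid else lo <- mid
      }
      hi
    }, numeric(1))
  }
  tibble::tibble(clone_id = seq_len(n_clones), count = as.numeric(counts))
}
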