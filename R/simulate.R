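#' @useDynLib clonedyn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
NULL

with_optional_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

snapshots_tibble <- function(time, id, size, t_recruit, zero_insertions = NULL) {
  out <- tibble::tibble(
    time = time, clone_id = id, t_recruit = t_recruit, size = size
  )
  if (!is.null(zero_insertions)) out$zero_insertions <- zero_insertions
  out
}

#' Exact stochastic simulation of repertoire formation
#'
#' Gillespie simulation of the coupled birth-death-immigration dynamics: clone
#' `i` proliferates at rate `C_i * b0 / N`, its cells die at rate `C_i * d`,
#' and new clones of size `C0` are recruited at rate `theta`. The repertoire
#' starts empty (or from `init`), and the state is recorded at each of
#' `config$record_times` (piecewise-constant between events). Extinct clones
#' are dropped from snapshots; the number of extinctions is reported as an
#' attribute `extinctions` alongside the event count `events`.
#'
#' @param config A [sim_config()] with `mode = "exact"`.
#' @param init Optional tibble/data frame of pre-existing clones with columns
#'   `size` (positive integers) and `t_recruit` (defaults to 0).
#' @return A tibble with columns `time`, `clone_id`, `t_recruit`, `size`
#'   (one row per living clone per record time), with attributes `events` and
#'   `extinctions`.
#' @examples
#' p <- formation_params(b0 = 100, d = 0.2, theta = 10)
#' sim <- simulate_exact(sim_config(p, t_end = 2, record_times = c(1, 2),
#'                                  seed = 1))
#' @export
simulate_exact <- function(config, init = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mode != "exact")
    stop("config$mode must be 'exact'", call. = FALSE)
  p <- config$params
  init_sizes <- integer(0)
  init_trec <- numeric(0)
  if (!is.null(init)) {
    stopifnot(is.data.frame(init), "size" %in% names(init))
    init_sizes <- as.integer(init$size)
    stopifnot(all(init_sizes >= 1))
    init_trec <- if ("t_recruit" %in% names(init)) init$t_recruit
                 else rep(0, length(init_sizes))
  }
  res <- with_optional_seed(config$seed,
    simulate_exact_cpp(p$b0, p$d, p$theta, p$C0, config$record_times,
                       init_sizes, init_trec))
  out <- purrr::map2_dfr(seq_along(config$record_times), config$record_times,
    function(k, tk) snapshots_tibble(tk, res$id[[k]], res$size[[k]],
                                     res$t_recruit[[k]]))
  attr(out, "events") <- res$n_events
  attr(out, "extinctions") <- res$n_extinct
  out
}

#' Mean-field simulation of repertoire formation
#'
#' Simulates each clone independently as a birth-death process with the
#' time-dependent per-cell birth rate `b0 / N(t)`, where `N(t)` is the
#' deterministic mean total size [mean_total_size()]. This mean-field
#' competition approximation decouples clones while retaining full demographic
#' stochasticity at the clone level; its clone-size distributions agree with
#' the exact simulation up to the single largest clone. Event times are drawn
#' by thinning an inhomogeneous Poisson process under the stepwise-constant
#' majorant rate evaluated at the previous event (valid because the birth
#' rate decreases monotonically as the repertoire fills). Recruitment times
#' form a homogeneous Poisson process of rate `theta` on `(0, t_end]`;
#' recruitment at exactly `t = 0` (where the rate diverges) has probability
#' zero and is excluded.
#'
#' @param config A [sim_config()] with `mode = "meanfield"`.
#' @param p0_fun Optional function mapping a recruitment time to a
#'   zero-insertion probability (e.g. `function(t) p0_of_time(t, cp)`); when
#'   supplied, snapshots carry a logical `zero_insertions` column.
#' @return A tibble with columns `time`, `clone_id`, `t_recruit`, `size`
#'   (and optionally `zero_insertions`), one row per living clone per record
#'   time.
#' @examples
#' p <- formation_params(b0 = 1000, d = 0.2, theta = 100)
#' cfg <- sim_config(p, t_end = 2, record_times = 2, seed = 1,
#'                   mode = "meanfield")
#' sim <- simulate_meanfield(cfg)
#' @export
simulate_meanfield <- function(config, p0_fun = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mode != "meanfield")
    stop("config$mode must be 'meanfield'", call. = FALSE)
  p <- config$params
  res <- with_optional_seed(config$seed, {
    r <- simulate_meanfield_cpp(p$b0, p$d, p$theta, p$C0, config$record_times)
    if (!is.null(p0_fun) && length(r$t_recruit) > 0)
      r$zero <- stats::runif(length(r$t_recruit)) < p0_fun(r$t_recruit)
    r
  })
  M <- length(res$t_recruit)
  purrr::map2_dfr(seq_along(config$record_times), config$record_times,
    function(k, tk) {
      sz <- if (M > 0) res$sizes[, k] else integer(0)
      alive <- which(sz > 0)
      snapshots_tibble(tk, alive, sz[alive], res$t_recruit[alive],
                       if (!is.null(res$zero)) res$zero[alive])
    })
}

#' Replicated single-clone mean-field trajectories
#'
#' Simulates `n_reps` independent clones, all recruited at `t_recruit`, under
#' the mean-field birth-death dynamics, and returns their sizes at
#' `record_times`. Used as a Monte-Carlo oracle against the deterministic
#' growth law [clone_growth()].
#'
#' @param t_recruit Recruitment time (years), strictly positive.
#' @param record_times Strictly increasing recording times `>= t_recruit`.
#' @param params A [formation_params()] object.
#' @param n_reps Number of replicate clones.
#' @param seed Optional integer seed.
#' @return An `n_reps x length(record_times)` integer matrix of sizes
#'   (0 = extinct).
#' @export
meanfield_clone_replicates <- function(t_recruit, record_times, params,
                                       n_reps = 1000, seed = NULL) {
  stopifnot(inherits(params, "formation_params"))
  if (t_recruit <= 0)
    stop("t_recruit must be strictly positive (the mean-field birth rate ",
         "diverges at t = 0)", call. = FALSE)
  with_optional_seed(seed,
    meanfield_clone_cpp(t_recruit, params$C0, params$b0, params$d,
                        params$theta, record_times, n_reps))
}

#' Geometric Brownian motion trajectories of log clone sizes
#'
#' Euler update of the Langevin dynamics `dx = f0 dt + sqrt(2*sigma2) dW`,
#' which is exact for this linear stochastic differential equation at any step
#' size: `x(t + dt) = x(t) + f0*dt + sqrt(2*sigma2*dt) * Z`.
#'
#' @param params A [fluct_params()] object (`sigma2 >= 0`; `sigma2 = 0` gives
#'   deterministic drift).
#' @param x0 Numeric vector of initial log sizes (one clone per element).
#' @param dt_grid Strictly increasing vector of observation times (years);
#'   the first entry is the time of `x0`.
#' @param seed Optional integer seed.
#' @return A tibble with columns `clone_id`, `time`, `x` (log clone size).
#' @examples
#' fp <- fluct_params(f0 = 0, sigma2 = 0.08)
#' simulate_fluctuating(fp, x0 = rep(0, 5), dt_grid = seq(0, 1, 0.25), seed = 1)
#' @export
simulate_fluctuating <- function(params, x0, dt_grid, seed = NULL) {
  stopifnot(inherits(params, "fluct_params"))
  if (params$sigma2 < 0) stop("sigma2 must be non-negative", call. = FALSE)
  dt_grid <- as.numeric(dt_grid)
  if (length(dt_grid) < 2 || is.unsorted(dt_grid, strictly = TRUE))
    stop("dt_grid must be strictly increasing with >= 2 times", call. = FALSE)
  n <- length(x0)
  k <- length(dt_grid)
  xmat <- with_optional_seed(seed, {
    m <- matrix(0, n, k)
    m[, 1] <- x0
    for (j in 2:k) {
      dt <- dt_grid[j] - dt_grid[j - 1]
      m[, j] <- m[, j - 1] + params$f0 * dt +
        sqrt(2 * params$sigma2 * dt) * stats::rnorm(n)
    }
    m
  })
  tibble::tibble(
    clone_id = rep(seq_len(n), times = k),
    time = rep(dt_grid, each = n),
    x = as.vector(xmat)
  )
}
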