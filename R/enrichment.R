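# Zero-insertion enrichment: rank binning, weighted sigmoid fitting of the
# relaxation profile, rescaling collapse, and a bootstrap regression helper.

#' Rank-binned zero-insertion fractions
#'
#' Within each individual, clones are ranked by descending read count (ties
#' keep their input order) and assigned to non-overlapping rank bins of width
#' `rank_bin_width` (rank 1-500, 501-1000, ...). Clones are then pooled
#' across individuals within each (age bin, rank bin) cell, and the fraction
#' of zero-insertion clones is reported with its binomial standard error
#' `sqrt(p*(1-p)/n)`; cells where the fraction is exactly 0 or 1 get a
#' half-count pseudocount SE floor so every cell carries a positive weight.
#'
#' @param samples A cohort tibble as from [sample_cohort()] (columns
#'   `individual_id`, `age`, `count`, `zero_insertions`).
#' @param rank_bin_width Width of the clone-size rank bins.
#' @param age_bins Age bin edges (years); default decade brackets.
#' @return An `enrichment_table` tibble with columns `age_mid`, `rank_lo`,
#'   `rank_hi`, `rank_mid`, `fraction_zero`, `se`, `n_clones`.
#' @export
bin_zero_fraction <- function(samples, rank_bin_width = 500,
                              age_bins = seq(0, 80, by = 10)) {
  stopifnot(all(c("individual_id", "age", "count", "zero_insertions") %in%
                names(samples)))
  stopifnot(rank_bin_width >= 1)
  out <- samples |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::mutate(
      rank = rank(-.data$count, ties.method = "first"),
      rank_bin = (.data$rank - 1) %/% rank_bin_width
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      age_bin = findInterval(.data$age, age_bins, rightmost.closed = TRUE)
    ) |>
    dplyr::filter(.data$age_bin >= 1, .data$age_bin < length(age_bins)) |>
    dplyr::group_by(.data$age_bin, .data$rank_bin) |>
    dplyr::summarise(
      n_clones = dplyr::n(),
      k_zero = sum(.data$zero_insertions),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      age_mid = (age_bins[.data$age_bin] + age_bins[.data$age_bin + 1]) / 2,
      rank_lo = .data$rank_bin * rank_bin_width + 1,
      rank_hi = (.data$rank_bin + 1) * rank_bin_width,
      rank_mid = (.data$rank_lo + .data$rank_hi) / 2,
      fraction_zero = .data$k_zero / .data$n_clones,
      p_se = ifelse(.data$k_zero == 0 | .data$k_zero == .data$n_clones,
                    (.data$k_zero + 0.5) / (.data$n_clones + 1),
                    .data$fraction_zero),
      se = sqrt(.data$p_se * (1 - .data$p_se) / .data$n_clones)
    ) |>
    dplyr::select(dplyr::all_of(c("age_mid", "rank_lo", "rank_hi", "rank_mid",
                                  "fraction_zero", "se", "n_clones"))) |>
    dplyr::arrange(.data$age_mid, .data$rank_lo)
  class(out) <- c("enrichment_table", class(out))
  out
}

relaxation_predict <- function(theta_t, rank_mid, age_mid) {
  rp <- list(r_star = exp(theta_t[1]), tau_d = exp(theta_t[2]),
             p0_minus = stats::plogis(theta_t[3]),
             p0_plus = stats::plogis(theta_t[4]))
  u <- (log(rank_mid / rp$r_star) + age_mid / rp$tau_d) /
    (2 * sqrt(age_mid / rp$tau_d))
  (rp$p0_minus - rp$p0_plus) / 2 * erfc(u) + rp$p0_plus
}

#' Weighted sigmoid fit of the zero-insertion relaxation profile
#'
#' Fits the four parameters of [zero_insertion_profile()] (`r_star`, `tau_d`,
#' `p0_minus`, `p0_plus`) to a rank-binned enrichment table by weighted least
#' squares, minimizing `sum(w * (fraction - P0(rank_mid, age_mid))^2)` with
#' weights `w = 1 / (se + spec_error)^2`, where `spec_error` is a fixed model
#' specification error added to each cell's binomial SE. Rank and age are the
#' mid-values of their bins. `r_star` and `tau_d` are fitted on the log scale
#' and the plateaus on the logit scale (enforcing positivity and `[0, 1]`
#' bounds); Levenberg-Marquardt least squares is run from multiple starting
#' points and the best optimum kept. Standard errors come from the Jacobian
#' at the optimum, propagating the stated per-cell uncertainties
#' (`se + spec_error`) as absolute errors, and are mapped to the natural
#' scale by the delta method; 95% intervals are computed on the transformed
#' scale and mapped back.
#'
#' @param table An `enrichment_table` from [bin_zero_fraction()] (or any data
#'   frame with columns `rank_mid`, `age_mid`, `fraction_zero`, `se`).
#' @param spec_error Fixed model specification error added to each SE.
#' @param n_starts Number of starting points (`>= 5` recommended).
#' @return An object of class `relaxation_fit` with elements `estimate`
#'   (named list), `std_error`, `conf_low`, `conf_high`, `wrss`, `n`,
#'   `converged`, `table`, `spec_error`. Supports [generics::tidy()],
#'   [generics::glance()] and `autoplot()`.
#' @export
fit_relaxation <- function(table, spec_error = 2e-3, n_starts = 6) {
  need <- c("rank_mid", "age_mid", "fraction_zero", "se")
  stopifnot(all(need %in% names(table)))
  if (nrow(table) < 8 || length(unique(table$age_mid)) < 2)
    stop("need at least 8 rows spanning at least 2 age bins", call. = FALSE)
  w <- 1 / (table$se + spec_error)^2
  sw <- sqrt(w)
  resid_fn <- function(theta_t) {
    sw * (table$fraction_zero -
            relaxation_predict(theta_t, table$rank_mid, table$age_mid))
  }
  p_hi <- max(table$fraction_zero)
  p_lo <- min(table$fraction_zero)
  clip <- function(p) pmin(pmax(p, 1e-4), 1 - 1e-4)
  r_starts <- stats::quantile(table$rank_mid,
                              seq(0.1, 0.9, length.out = n_starts))
  t_starts <- exp(seq(log(1), log(40), length.out = n_starts))
  starts <- lapply(seq_len(n_starts), function(i) {
    c(log(r_starts[[i]]), log(t_starts[[i]]),
      stats::qlogis(clip(p_hi)), stats::qlogis(clip(p_lo)))
  })
  fits <- lapply(starts, function(st) {
    tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0)
    stop("relaxation fit failed to converge from every start", call. = FALSE)
  dev <- vapply(fits, function(f) f$deviance, numeric(1))
  ok <- vapply(fits, function(f) f$info %in% 1:4, logical(1))
  if (!any(ok))
    stop("relaxation fit did not converge from any start; best weighted RSS ",
         format(min(dev)), call. = FALSE)
  best <- fits[ok][[which.min(dev[ok])]]
  theta <- best$par
  n <- nrow(table)
  # the weights are absolute uncertainties (binomial SE plus the fixed model
  # specification error), so the covariance is (J' W J)^-1 without rescaling
  # by the reduced chi-square
  covm <- tryCatch(solve(best$hessian), error = function(e)
    matrix(NA_real_, 4, 4))
  se_t <- sqrt(pmax(diag(covm), 0))
  ci_lo_t <- theta - 1.96 * se_t
  ci_hi_t <- theta + 1.96 * se_t
  back <- function(v) c(exp(v[1]), exp(v[2]),
                        stats::plogis(v[3]), stats::plogis(v[4]))
  est <- back(theta)
  # delta method on the natural scale
  deriv <- c(exp(theta[1]), exp(theta[2]),
             stats::dlogis(theta[3]), stats::dlogis(theta[4]))
  nm <- c("r_star", "tau_d", "p0_minus", "p0_plus")
  structure(
    list(estimate = stats::setNames(as.list(est), nm),
         std_error = stats::setNames(se_t * deriv, nm),
         conf_low = stats::setNames(back(ci_lo_t), nm),
         conf_high = stats::setNames(back(ci_hi_t), nm),
         wrss = best$deviance, n = n,
         converged = TRUE,
         table = table, spec_error = spec_error),
    class = "relaxation_fit"
  )
}

#' @export
print.relaxation_fit <- function(x, ...) {
  cat("Zero-insertion relaxation fit (weighted least squares)\n")
  cat(sprintf("  r*   = %.3g (SE %.2g), tau_d = %.3g yr (SE %.2g)\n",
              x$estimate$r_star, x$std_error[["r_star"]],
              x$estimate$tau_d, x$std_error[["tau_d"]]))
  cat(sprintf("  p0,- = %.4f (SE %.2g), p0,+ = %.4f (SE %.2g)\n",
              x$estimate$p0_minus, x$std_error[["p0_minus"]],
              x$estimate$p0_plus, x$std_error[["p0_plus"]]))
  cat(sprintf("  weighted RSS = %.4g over %d cells\n", x$wrss, x$n))
  invisible(x)
}

#' Rescaling collapse of the enrichment table
#'
#' Maps every (rank bin, age bin) cell onto the universal abscissa
#' `u = (log(r/r_star) + t/tau_d) / (2*sqrt(t/tau_d))` using fitted (or
#' known) parameters; on this axis the theory predicts all points to fall on
#' the single sigmoid `y(u) = delta_p0/2 * erfc(u) + p0_plus`.
#'
#' @param table An enrichment table (see [fit_relaxation()]).
#' @param fit A `relaxation_fit` or [relaxation_params()] object supplying
#'   `r_star`, `tau_d`, `p0_minus`, `p0_plus`.
#' @param curve_n Number of points at which the reference curve is sampled.
#' @return A list of class `enrichment_collapse` with `points` (tibble `u`,
#'   `fraction_zero`, `se`, `predicted`, `residual`) and `curve` (tibble `u`,
#'   `p0`).
#' @export
rescale_collapse <- function(table, fit, curve_n = 200) {
  pars <- if (inherits(fit, "relaxation_fit")) fit$estimate else unclass(fit)
  stopifnot(all(c("r_star", "tau_d", "p0_minus", "p0_plus") %in% names(pars)))
  u <- (log(table$rank_mid / pars$r_star) + table$age_mid / pars$tau_d) /
    (2 * sqrt(table$age_mid / pars$tau_d))
  dp <- pars$p0_minus - pars$p0_plus
  pred <- dp / 2 * erfc(u) + pars$p0_plus
  ug <- seq(min(u) - 0.5, max(u) + 0.5, length.out = curve_n)
  structure(
    list(points = tibble::tibble(u = u, fraction_zero = table$fraction_zero,
                                 se = table$se, predicted = pred,
                                 residual = table$fraction_zero - pred),
         curve = tibble::tibble(u = ug, p0 = dp / 2 * erfc(ug) + pars$p0_plus)),
    class = "enrichment_collapse"
  )
}

#' Ordinary least squares with case-resampling bootstrap intervals
#'
#' Fits `y ~ x` by OLS and obtains 95% percentile confidence intervals for
#' slope and intercept by case resampling: rows are resampled with
#' replacement `n_boot` times and the regression refitted on each resample.
#'
#' @param x,y Numeric vectors (`>= 3` points; `x` must have positive
#'   variance).
#' @param n_boot Number of bootstrap resamples.
#' @param seed Optional integer seed.
#' @return A tibble with rows `slope` and `intercept` and columns `term`,
#'   `estimate`, `conf_low`, `conf_high`.
#' @examples
#' bootstrap_regression(1:10, 2 * (1:10) + 1, n_boot = 200, seed = 1)
#' @export
bootstrap_regression <- function(x, y, n_boot = 1000, seed = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0)
    stop("x has zero variance; slope is undefined", call. = FALSE)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  boots <- with_optional_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(length(x), replace = TRUE)
      if (stats::var(x[idx]) == 0) return(c(NA_real_, NA_real_))
      stats::coef(stats::lm(y[idx] ~ x[idx]))
    }, numeric(2))
  })
  qs <- apply(boots, 1, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = as.numeric(co),
    conf_low = qs[1, ],
    conf_high = qs[2, ]
  )
}
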