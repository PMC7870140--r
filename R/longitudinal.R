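# Longitudinal clone-size fluctuation analysis: log-foldchange variance
# curves, fluctuation-strength estimation, and rank-origin composition of the
# largest clones.

# Normalize a long-format trajectory table to per-timepoint log frequencies.
# `value` selects the measurement column: "count" (read counts, converted to
# within-timepoint frequencies before the log) or "x" (already log sizes).
traj_log_values <- function(data, value) {
  stopifnot(all(c("clone_id", "time") %in% names(data)),
            value %in% names(data))
  if (value == "count") {
    data |>
      dplyr::group_by(.data$time) |>
      dplyr::mutate(logval = ifelse(.data$count > 0,
                                    log(.data$count / sum(.data$count)),
                                    NA_real_),
                    detected = .data$count > 0) |>
      dplyr::ungroup()
  } else {
    dplyr::mutate(data, logval = .data[[value]],
                  detected = is.finite(.data[[value]]))
  }
}

#' Variance of log-foldchanges in clone size versus time difference
#'
#' For the `top_n` largest clones at the reference timepoint (by default the
#' second sample) that were already detected at the earliest timepoint --
#' excluding recently expanded clones whose transient dynamics would
#' confound the estimate -- computes the variance across clones of
#' `log(f(t)/f(t_ref))` for every timepoint after the reference, where `f`
#' is the within-sample clone frequency (or `exp(x)` when log sizes are
#' supplied directly).
#'
#' @param data Long-format trajectories: columns `clone_id`, `time` and
#'   either `count` (reads; zero = not detected) or a log-size column named
#'   by `value`.
#' @param ref_index Index (in time order) of the reference timepoint.
#' @param earliest_index Index of the timepoint used for the detection
#'   filter.
#' @param top_n Number of top clones at the reference timepoint to follow.
#' @param value Measurement column: `"count"` or the name of a log-size
#'   column (e.g. `"x"` from [generate_longitudinal()]).
#' @param min_clones Minimum number of eligible clones.
#' @return A tibble with columns `dt` (years since the reference), `variance`
#'   and `n_clones`.
#' @export
logfold_variance_curve <- function(data, ref_index = 2, earliest_index = 1,
                                   top_n = 250, value = "count",
                                   min_clones = 20) {
  d <- traj_log_values(data, value)
  times <- sort(unique(d$time))
  stopifnot(ref_index >= 1, ref_index <= length(times),
            earliest_index >= 1, earliest_index <= length(times))
  t_ref <- times[ref_index]
  t_early <- times[earliest_index]
  ref <- d |> dplyr::filter(.data$time == t_ref, .data$detected)
  early_ids <- d |>
    dplyr::filter(.data$time == t_early, .data$detected) |>
    dplyr::pull("clone_id")
  eligible <- ref |>
    dplyr::filter(.data$clone_id %in% early_ids) |>
    dplyr::slice_max(.data$logval, n = top_n, with_ties = FALSE)
  if (nrow(eligible) < min_clones)
    stop("only ", nrow(eligible), " eligible clones (need at least ",
         min_clones, ")", call. = FALSE)
  ref_vals <- stats::setNames(eligible$logval, eligible$clone_id)
  d |>
    dplyr::filter(.data$time > t_ref,
                  .data$clone_id %in% eligible$clone_id, .data$detected) |>
    dplyr::mutate(lfc = .data$logval -
                    ref_vals[as.character(.data$clone_id)]) |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(variance = stats::var(.data$lfc),
                     n_clones = dplyr::n(), .groups = "drop") |>
    dplyr::transmute(dt = .data$time - t_ref, variance = .data$variance,
                     n_clones = .data$n_clones)
}

#' Estimate the clonal growth-rate fluctuation strength
#'
#' Linear regression of the log-foldchange variance on time difference: the
#' model predicts `var = 2*sigma2*dt + 2*sigma_S^2`, so the fluctuation
#' strength is half the slope and the sample-to-sample measurement variance
#' is half the intercept. Negative estimates are clipped to zero with a
#' warning flag. Confidence intervals come from [bootstrap_regression()].
#'
#' @param curve Output of [logfold_variance_curve()] (`>= 3` rows).
#' @param n_boot Bootstrap resamples for the interval.
#' @param seed Optional integer seed for the bootstrap.
#' @return An object of class `fluctuation_fit` with elements `sigma2_hat`,
#'   `sampling_var_hat`, `slope`, `intercept`, `conf_low`, `conf_high`
#'   (bounds on `sigma2_hat`), `clipped`, `curve`. Supports
#'   [generics::tidy()], [generics::glance()] and `autoplot()`.
#' @export
estimate_fluctuation_strength <- function(curve, n_boot = 1000, seed = NULL) {
  stopifnot(all(c("dt", "variance") %in% names(curve)))
  if (nrow(curve) < 3)
    stop("need at least 3 time differences", call. = FALSE)
  boot <- bootstrap_regression(curve$dt, curve$variance, n_boot = n_boot,
                               seed = seed)
  slope <- boot$estimate[boot$term == "slope"]
  intercept <- boot$estimate[boot$term == "intercept"]
  clipped <- FALSE
  s2 <- slope / 2
  if (s2 < 0) {
    warning("negative variance slope; sigma2 clipped to 0", call. = FALSE)
    s2 <- 0
    clipped <- TRUE
  }
  sv <- intercept / 2
  if (sv < 0) {
    warning("negative intercept; sampling variance clipped to 0",
            call. = FALSE)
    sv <- 0
    clipped <- TRUE
  }
  structure(
    list(sigma2_hat = s2, sampling_var_hat = sv,
         slope = slope, intercept = intercept,
         conf_low = boot$conf_low[boot$term == "slope"] / 2,
         conf_high = boot$conf_high[boot$term == "slope"] / 2,
         clipped = clipped, curve = curve),
    class = "fluctuation_fit"
  )
}

#' @export
print.fluctuation_fit <- function(x, ...) {
  cat(sprintf(
    "Fluctuation strength: sigma2 = %.4g /yr [95%% CI %.4g, %.4g], sigma_S^2 = %.4g%s\n",
    x$sigma2_hat, x$conf_low, x$conf_high, x$sampling_var_hat,
    if (x$clipped) " [clipped]" else ""))
  invisible(x)
}

#' Origin composition of the largest clones
#'
#' Classifies, for every timepoint after the earliest, the `top_n` largest
#' clones by where they ranked at the earliest timepoint: a clone-size rank
#' bin, or "ND" (not detected: zero reads at the earliest timepoint, no
#' imputation). Fractions sum to one at every timepoint; slow fluctuations
#' show up as a small ND fraction with most top clones originating from the
#' top origin bins.
#'
#' @param data Long-format trajectories (see [logfold_variance_curve()]).
#' @param top_n Number of top clones classified at each later timepoint.
#' @param origin_bins Increasing rank-bin edges; origin bin `j` is ranks
#'   `[origin_bins[j], origin_bins[j+1])`.
#' @param value Measurement column (`"count"` or a log-size column).
#' @return A tibble with columns `time`, `origin` (factor; rank-bin label or
#'   `"ND"`) and `fraction`.
#' @export
rank_origin_composition <- function(data, top_n = 1000,
                                    origin_bins = c(1, 101, 1001, 10001),
                                    value = "count") {
  d <- traj_log_values(data, value)
  times <- sort(unique(d$time))
  if (length(times) < 2) stop("need at least 2 timepoints", call. = FALSE)
  t0 <- times[1]
  first <- d |> dplyr::filter(.data$time == t0, .data$detected)
  first_rank <- stats::setNames(rank(-first$logval, ties.method = "first"),
                                first$clone_id)
  edges <- c(origin_bins, Inf)
  labels <- c(vapply(seq_len(length(edges) - 1), function(j) {
    if (is.finite(edges[j + 1]))
      sprintf("%d-%d", edges[j], edges[j + 1] - 1)
    else sprintf(">=%d", edges[j])
  }, character(1)), "ND")
  purrr::map_dfr(times[-1], function(tk) {
    top <- d |>
      dplyr::filter(.data$time == tk, .data$detected) |>
      dplyr::slice_max(.data$logval, n = top_n, with_ties = FALSE)
    r0 <- first_rank[as.character(top$clone_id)]
    bin <- ifelse(is.na(r0), length(labels), findInterval(r0, edges))
    tab <- tabulate(bin, nbins = length(labels))
    tibble::tibble(time = tk,
                   origin = factor(labels, levels = labels),
                   fraction = tab / nrow(top))
  })
}
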