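# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.exponent_fit <- function(x, ...) {
  tibble::tibble(term = "alpha", estimate = x$alpha, std.error = x$se)
}

#' @export
glance.exponent_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, se = x$se, c_min = x$c_min,
                 m_used = x$m_used, logLik = x$loglik, flagged = x$flagged)
}

#' @export
tidy.relaxation_fit <- function(x, ...) {
  nm <- names(x$std_error)
  tibble::tibble(
    term = nm,
    estimate = unlist(x$estimate[nm], use.names = FALSE),
    std.error = unname(x$std_error[nm]),
    conf.low = unname(x$conf_low[nm]),
    conf.high = unname(x$conf_high[nm])
  )
}

#' @export
glance.relaxation_fit <- function(x, ...) {
  tibble::tibble(wrss = x$wrss, n = x$n, spec_error = x$spec_error,
                 converged = x$converged)
}

#' @export
tidy.fluctuation_fit <- function(x, ...) {
  tibble::tibble(
    term = c("sigma2", "sampling_var"),
    estimate = c(x$sigma2_hat, x$sampling_var_hat),
    conf.low = c(x$conf_low, NA_real_),
    conf.high = c(x$conf_high, NA_real_)
  )
}

#' @export
glance.fluctuation_fit <- function(x, ...) {
  tibble::tibble(sigma2_hat = x$sigma2_hat,
                 sampling_var_hat = x$sampling_var_hat,
                 slope = x$slope, intercept = x$intercept,
                 n_dt = nrow(x$curve), clipped = x$clipped)
}
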