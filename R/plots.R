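# ggplot2 diagnostics for samples and fitted objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Rank-abundance plot
#'
#' Log-log plot of clone-size rank against (optionally normalized) clone
#' size, the standard display of the clone-size scaling law.
#'
#' @inheritParams rank_size
#' @return A ggplot object.
#' @export
plot_rank_size <- function(data, normalize = FALSE, memory_fraction = NULL) {
  rs <- rank_size(data, normalize = normalize,
                  memory_fraction = memory_fraction)
  ggplot2::ggplot(rs, ggplot2::aes(x = .data$size, y = .data$rank)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = if (normalize) "normalized clone size" else "clone size",
                  y = "rank") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.exponent_fit <- function(object, ...) {
  rs <- rank_size(object$counts)
  rs_fit <- dplyr::filter(rs, .data$count >= object$c_min)
  # reference power law rank ~ C^-alpha anchored at the trimming threshold
  anchor <- max(rs_fit$rank)
  ref <- tibble::tibble(
    size = exp(seq(log(object$c_min), log(max(rs$size)), length.out = 50)))
  ref$rank <- anchor * (ref$size / object$c_min)^(-object$alpha)
  plot_rank_size(object$counts) +
    ggplot2::geom_line(data = ref, colour = "red", linetype = 2) +
    ggplot2::labs(subtitle = sprintf("alpha = %.3f (SE %.3f), C_min = %d",
                                     object$alpha, object$se, object$c_min))
}

#' @export
autoplot.enrichment_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$rank_mid, y = .data$fraction_zero,
                               colour = factor(.data$age_mid),
                               group = .data$age_mid)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$fraction_zero - .data$se,
                                          ymax = .data$fraction_zero + .data$se),
                             size = 0.2) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "clone size rank (bin mid)",
                  y = "fraction zero-insertion clones",
                  colour = "age (yr)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.relaxation_fit <- function(object, ...) {
  autoplot(rescale_collapse(object$table, object))
}

#' @export
autoplot.enrichment_collapse <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$u, y = .data$fraction_zero)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$fraction_zero - .data$se,
                                          ymax = .data$fraction_zero + .data$se),
                             size = 0.2, alpha = 0.7) +
    ggplot2::geom_line(data = object$curve,
                       ggplot2::aes(x = .data$u, y = .data$p0),
                       colour = "black") +
    ggplot2::labs(x = "rescaled rank-age coordinate u",
                  y = "fraction zero-insertion clones") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fluctuation_fit <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$dt, y = .data$variance)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "red", linetype = 2) +
    ggplot2::labs(x = "time difference (yr)",
                  y = "variance of log-foldchange",
                  subtitle = sprintf("sigma2 = %.3g/yr, sigma_S^2 = %.3g",
                                     object$sigma2_hat,
                                     object$sampling_var_hat)) +
    ggplot2::theme_minimal()
}
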