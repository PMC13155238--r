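#' Plot substrate rate ratios
#'
#' Forest-style display of exponentiated substrate contrasts with their Wald
#' intervals; the dashed line at 1 marks parity with the reference substrate.
#'
#' @param ratios A tibble from [rate_ratios()].
#' @return A ggplot object.
#' @export
plot_rate_ratios <- function(ratios) {
  ratios %>%
    dplyr::mutate(substrateCategory = stats::reorder(.data$substrateCategory,
                                                     .data$rate_ratio)) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$rate_ratio,
                                 y = .data$substrateCategory)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2, na.rm = TRUE) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "rate ratio vs reference (per unit effort)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the substrate diversity panel
#'
#' @param div A tibble from [substrate_diversity()].
#' @return A ggplot object.
#' @export
plot_diversity <- function(div) {
  div %>%
    dplyr::mutate(order_q = paste0("q = ", .data$q),
                  panel = ifelse(.data$panel == "size",
                                 "common sample size", "common coverage")) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$substrateCategory,
                                 y = .data$estimate)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper), width = 0.2) +
    ggplot2::geom_point() +
    ggplot2::facet_grid(order_q ~ panel, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Hill number (effective species)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.rank_summary <- function(object, ...) {
  object %>%
    dplyr::mutate(substrateCategory = stats::reorder(.data$substrateCategory,
                                                     -.data$median_rank)) %>%
    ggplot2::ggplot(ggplot2::aes(y = .data$substrateCategory)) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$rank_95_low,
                                         xmax = .data$rank_95_high),
                            linewidth = 0.4, colour = "grey60") +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$rank_50_low,
                                         xmax = .data$rank_50_high),
                            linewidth = 1.4) +
    ggplot2::geom_point(ggplot2::aes(x = .data$median_rank), size = 2) +
    ggplot2::geom_point(ggplot2::aes(x = .data$weighted_median_rank),
                        shape = 5, size = 2) +
    ggplot2::labs(x = "bootstrap rank (1 = highest per-unit-effort mean)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.elevation_profile <- function(object, ...) {
  shares <- object$cells %>%
    dplyr::mutate(share = .data$y / .data$exposure)
  peak <- max(object$grid$intensity)
  scale_to <- max(shares$share)
  ggplot2::ggplot() +
    ggplot2::geom_point(data = shares,
                        ggplot2::aes(x = .data$mid, y = .data$share),
                        alpha = 0.4) +
    ggplot2::geom_line(data = object$grid,
                       ggplot2::aes(x = .data$elevation,
                                    y = .data$intensity / peak * scale_to),
                       colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$modeElev, linetype = "dotted") +
    ggplot2::labs(title = object$species, x = "elevation (m)",
                  y = "share of records / scaled relative intensity") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot2::ggplot(object$deciles,
                  ggplot2::aes(x = .data$mean_predicted,
                               y = .data$mean_observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -1, size = 3) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mean predicted count (decile)",
                  y = "mean observed count",
                  size = "n") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.residual_diagnostics <- function(object, ...) {
  n <- length(object$residuals)
  tibble::tibble(theoretical = stats::ppoints(n),
                 empirical = sort(object$residuals)) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$theoretical, y = .data$empirical)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "Uniform(0,1) quantiles",
                  y = "randomized quantile residuals") +
    ggplot2::theme_minimal()
}
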