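#' @import ggplot2
NULL

#' Forest-style plot of an MSM fit
#'
#' Hazard ratios with 95% confidence intervals for the exposure terms of a
#' fitted model, on a log scale with a reference line at 1.
#'
#' @param object An `msm_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot msm_fit
#' @export
autoplot.msm_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$hazard_ratio, y = .data$term)) +
    geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    geom_pointrange(aes(xmin = .data$conf_low, xmax = .data$conf_high)) +
    scale_x_log10() +
    labs(x = "Hazard ratio (95% CI)", y = NULL, title = object$label) +
    theme_minimal()
}

#' Dose-response curve plot
#'
#' Fitted hazard-ratio curve against cumulative DDD with its pointwise
#' confidence band.
#'
#' @param object A `dose_response` from [spline_dose_response()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dose_response
#' @export
autoplot.dose_response <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$cum_ddd, y = .data$hazard_ratio)) +
    geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    geom_ribbon(aes(ymin = .data$conf_low, ymax = .data$conf_high),
                alpha = 0.2) +
    geom_line() +
    labs(x = "Cumulative DDD", y = "Hazard ratio vs dose 0") +
    theme_minimal()
}

#' Plot per-interval log-weight diagnostics
#'
#' Mean of log stabilized and non-stabilized weights by interval with a
#' +/- 1 SD ribbon; well-behaved stabilized weights stay near 0.
#'
#' @param weights A `weight_set`.
#' @return A ggplot.
#' @export
plot_weight_diagnostics <- function(weights) {
  d <- weight_diagnostics(weights) |>
    tidyr::pivot_longer(cols = c("mean_log_sw", "mean_log_w"),
                        names_to = "type", values_to = "mean_log") |>
    mutate(sd = ifelse(.data$type == "mean_log_sw",
                       .data$sd_log_sw, .data$sd_log_w),
           type = ifelse(.data$type == "mean_log_sw",
                         "stabilized", "non-stabilized"))
  ggplot(d, aes(x = .data$k, y = .data$mean_log, colour = .data$type,
                fill = .data$type)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_ribbon(aes(ymin = .data$mean_log - .data$sd,
                    ymax = .data$mean_log + .data$sd),
                alpha = 0.15, colour = NA) +
    geom_line() + geom_point() +
    labs(x = "Interval", y = "Mean log IPT weight",
         colour = NULL, fill = NULL) +
    theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
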