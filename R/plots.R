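#' Plot an exposure-response curve
#'
#' Centered log-odds of anemia against annual mean temperature with the
#' pointwise 95% band from the spline fit.
#'
#' @param object an `er_curve`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.er_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$temperature, y = .data$log_odds)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "Annual mean temperature (°C)",
                  y = "Log-odds of anemia (centered)",
                  subtitle = sprintf("Linearity F-test p = %.3g",
                                     object$p_linearity)) +
    ggplot2::theme_minimal()
}

#' Plot a burden projection
#'
#' Excess anemia cases per 100,000 person-years by decade and scenario with
#' empirical 95% CIs, for one aggregation scope.
#'
#' @param object a `burden_result`.
#' @param scope_level which aggregation level to show (default `"total"`).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.burden_result <- function(object, scope_level = "total", ...) {
  d <- tidy(object)
  d <- d[d$scope_level == scope_level, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$decade, y = .data$burden_per_100k,
                                  fill = .data$scenario)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$eci_low,
                                        ymax = .data$eci_high),
                           position = ggplot2::position_dodge(width = 0.8),
                           width = 0.25, linewidth = 0.3) +
    ggplot2::facet_wrap(~scope, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Excess cases per 100,000 person-years",
                  fill = "Scenario") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot ensemble warming trajectories
#'
#' Ensemble-mean ΔT per year and scenario (city means), with the
#' across-member interquartile band.
#'
#' @param deltas a ΔT tibble from [delta_t()].
#' @return A ggplot.
#' @export
plot_delta_t <- function(deltas) {
  d <- dplyr::summarise(
    dplyr::group_by(deltas, .data$scenario, .data$gcm_id, .data$year),
    delta_t = mean(.data$delta_t), .groups = "drop")
  d <- dplyr::summarise(
    dplyr::group_by(d, .data$scenario, .data$year),
    mid = mean(.data$delta_t),
    lo = quantile(.data$delta_t, 0.25), hi = quantile(.data$delta_t, 0.75),
    .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$year, y = .data$mid,
                                  colour = .data$scenario,
                                  fill = .data$scenario)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "ΔT vs baseline (°C)",
                  colour = "Scenario", fill = "Scenario") +
    ggplot2::theme_minimal()
}

#' Forest-style plot of association fits
#'
#' Odds ratios per +1 degC with 95% CIs across scopes or outcomes, from a
#' list of `assoc_fit` objects.
#'
#' @param fits a list of `assoc_fit` objects.
#' @return A ggplot.
#' @export
plot_association_forest <- function(fits) {
  d <- dplyr::bind_rows(lapply(fits, tidy))
  d$label <- paste(d$scope_value, d$outcome)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or_per_degc, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, linewidth = 0.3) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$or_low,
                                          xmax = .data$or_high)) +
    ggplot2::labs(x = "OR per +1 °C (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
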