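#' Plot the posterior concentration-fatality curve
#'
#' Posterior mean and 95% credible band of the probability of death as a
#' function of peak whole-blood parent-drug concentration (log10 x-axis).
#'
#' @param object A `cq_mortality_fit`.
#' @param conc_grid Concentration grid (umol/L).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cq_mortality_fit <- function(object,
                                      conc_grid = exp(seq(log(1), log(100),
                                                          length.out = 150)),
                                      ...) {
  curve <- mortality_curve(object, conc_grid)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$conc_umol_L)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low,
                                      ymax = .data$conf_high),
                         fill = "firebrick", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p_mean), colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Peak whole-blood chloroquine (µmol/L)",
                  y = "P(death)",
                  title = "Posterior concentration-fatality curve") +
    ggplot2::theme_minimal()
}

#' Plot the fitted QRS concentration-effect curve
#'
#' @param object A `cq_qrs_fit`.
#' @param conc_grid Concentration grid (umol/L).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cq_qrs_fit <- function(object,
                                conc_grid = exp(seq(log(0.5), log(150),
                                                    length.out = 150)),
                                ...) {
  draws <- object$draws
  curve <- purrr::map_dfr(conc_grid, function(cc) {
    m <- emax_mean(cc, draws)
    tibble::tibble(conc_umol_L = cc, qrs_mean = mean(m),
                   conf_low = unname(quantile(m, 0.025)),
                   conf_high = unname(quantile(m, 0.975)))
  })
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$conc_umol_L)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low,
                                      ymax = .data$conf_high),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$qrs_mean), colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Whole-blood chloroquine (µmol/L)",
                  y = "Mean QRS duration (msec)",
                  title = "Posterior QRS Emax curve") +
    ggplot2::theme_minimal()
}

#' Histogram of simulated peak concentrations
#'
#' @param object A `cq_cmax_sample`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cq_cmax_sample <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$cmax_umol_L)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40", colour = "white") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "C_max, whole blood (µmol/L)", y = "Simulated individuals",
      title = sprintf("Simulated C_max: %s, %g kg (%s)",
                      attr(object, "regimen_id"), attr(object, "weight_kg"),
                      attr(object, "model_id"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot projected fatality by body weight and regimen
#'
#' @param object A `cq_risk_table` from [weight_risk_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cq_risk_table <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$weight_kg,
                               y = .data$fatality_per1000_mean,
                               colour = .data$regimen_id,
                               fill = .data$regimen_id)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$fatality_per1000_lo,
                                      ymax = .data$fatality_per1000_hi),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$model_id)) +
    ggplot2::labs(x = "Body weight (kg)",
                  y = "Expected fatality per 1000 (truncated at 1%)",
                  colour = "Regimen", fill = "Regimen") +
    ggplot2::theme_minimal()
}
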