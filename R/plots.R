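# ggplot2 conveniences for each result type.

#' @describeIn fit_kill_model Observed points and the fitted
#'   kill-versus-BVF curve.
#' @param object A `kill_fit` object (for `autoplot`).
#' @method autoplot kill_fit
#' @export
autoplot.kill_fit <- function(object, ...) {
  if (!object$converged) {
    abort("Cannot plot a fit that did not converge.",
          class = "vasckill_validation_error")
  }
  grid <- seq(max(min(object$data$bvf) * 0.5, 1e-4),
              min(max(object$data$bvf) * 1.2, 0.999), length.out = 200)
  curve <- predict_curve(object$fkill_m_hat, object$rb_over_L_hat, grid)
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$bvf,
                                    y = .data$dead_fraction)) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$bvf, y = .data$f_kill),
                       inherit.aes = FALSE) +
    ggplot2::labs(x = "Blood volume fraction",
                  y = "Fraction of tumor volume killed",
                  title = sprintf(
                    "Calibrated kill model (R² = %.2f)",
                    object$r_squared))
  if ("line" %in% names(object$data)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$line), size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p
}

#' @describeIn fit_hill_ic50 Dose-response points with the fitted 4PL
#'   curve on a log concentration axis.
#' @param object An `ic50_fit` object (for `autoplot`).
#' @param ... Unused.
#' @method autoplot ic50_fit
#' @export
autoplot.ic50_fit <- function(object, ...) {
  if (!object$converged) {
    abort("Cannot plot a fit that did not converge.",
          class = "vasckill_validation_error")
  }
  conc <- object$data$concentration_nM
  grid <- exp(seq(log(min(conc)), log(max(conc)), length.out = 200))
  curve <- tibble(
    concentration_nM = grid,
    viability_fraction = hill_4pl(grid, object$top, object$bottom,
                                  object$ic50_nM, object$hill_slope))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$concentration_nM,
                               y = .data$viability_fraction)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = curve) +
    ggplot2::geom_vline(xintercept = object$ic50_nM, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Concentration (nM)", y = "Viability fraction",
                  title = sprintf("4PL fit, IC50 = %.3g nM",
                                  object$ic50_nM))
}

#' Plot the drug concentration profile around a vessel
#'
#' Normalized concentration \eqn{\sigma/\sigma_0} versus scaled radius for
#' one or more scaled vessel radii.
#'
#' @param rb_over_L Vector of scaled vessel radii.
#' @param r_max Outer scaled radius.
#' @return A ggplot object.
#' @examples
#' plot_concentration_profile(c(0.068, 0.125))
#' @export
plot_concentration_profile <- function(rb_over_L, r_max = 5) {
  profiles <- purrr::map_dfr(rb_over_L, function(a) {
    dplyr::mutate(concentration_profile(a, r_max = r_max),
                  rb_over_L = factor(a))
  })
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$scaled_radius,
                               y = .data$concentration,
                               colour = .data$rb_over_L)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Scaled radius r / L",
                  y = expression(sigma / sigma[0]),
                  colour = expression(r[b] / L))
}

#' Plot a sensitivity ranking
#'
#' Bar chart of mean absolute sensitivity coefficients from
#' [sensitivity_ranking()].
#'
#' @param ranking The tibble returned by [sensitivity_ranking()].
#' @return A ggplot object.
#' @examples
#' p <- model_params(0.038, 5, 40, 0.25)
#' plot_sensitivity_ranking(sensitivity_ranking(p))
#' @export
plot_sensitivity_ranking <- function(ranking) {
  check_columns(ranking, c("parameter", "mean_abs_S"), "ranking")
  ggplot2::ggplot(ranking,
                  ggplot2::aes(x = stats::reorder(.data$parameter,
                                                  -.data$mean_abs_S),
                               y = .data$mean_abs_S)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Mean |S|")
}
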