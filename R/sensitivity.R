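# Local sensitivity analysis of the kill fraction by single-parameter
# variation: perturb one parameter, hold the rest, and normalize the output
# change by the parameter change.

SENSITIVITY_PARAMS <- c("bvf", "rb_um", "L_um", "fkill_m")

#' Normalized local sensitivity coefficient
#'
#' Perturbs one model parameter by a relative amount \eqn{\delta} and
#' returns the normalized response
#' \deqn{S = \frac{(Y(p(1+\delta)) - Y(p)) / Y(p)}{\delta},}
#' with \eqn{Y} the closed-form kill fraction. The in-vitro kill fraction
#' enters the model as a pure multiplier, so its coefficient is 1 for every
#' reference and every \eqn{\delta}. `rb_um` and `L_um` are perturbed
#' independently in micrometres (not through their ratio).
#'
#' @param reference A [model_params()] object, the unperturbed parameter
#'   set.
#' @param parameter One of `"bvf"`, `"rb_um"`, `"L_um"`, `"fkill_m"`.
#' @param perturbation Non-zero signed relative change \eqn{\delta}
#'   (default +0.1); must keep the perturbed parameter valid (e.g.
#'   `bvf * (1 + perturbation) < 1`).
#' @param method `"forward"` (default) uses the one-sided quotient above;
#'   `"central"` uses \eqn{(Y(p(1+\delta)) - Y(p(1-\delta)))/(2\delta
#'   Y(p))}.
#' @return A one-row tibble with columns `parameter`, `perturbation`, `S`.
#' @examples
#' p <- model_params(0.038, 5, 40, 0.25)
#' sensitivity_coefficient(p, "bvf", 0.1)
#' sensitivity_coefficient(p, "fkill_m", 0.25) # S = 1 always
#' @export
sensitivity_coefficient <- function(reference, parameter,
                                    perturbation = 0.1,
                                    method = c("forward", "central")) {
  if (!inherits(reference, "model_params")) {
    abort("`reference` must be a model_params object.",
          class = "vasckill_validation_error")
  }
  parameter <- match.arg(parameter, SENSITIVITY_PARAMS)
  method <- match.arg(method)
  if (!is.numeric(perturbation) || length(perturbation) != 1L ||
      !is.finite(perturbation) || perturbation == 0) {
    abort("`perturbation` must be a single non-zero relative change.",
          class = "vasckill_domain_error")
  }
  y0 <- kill_fraction(reference)
  if (y0 == 0) {
    abort("Kill fraction is 0 at the reference; S is undefined.",
          class = "vasckill_domain_error")
  }
  # evaluate the model at the perturbed parameter set; fkill_m may leave
  # [0, 1] under perturbation — the model stays linear in it, so that is
  # well-defined — but geometry must remain valid
  y_at <- function(d) {
    p <- unclass(reference)
    p[[parameter]] <- p[[parameter]] * (1 + d)
    if (p$bvf >= 1 || p$bvf <= 0 || p$rb_um <= 0 || p$L_um <= 0) {
      abort(sprintf(
        "Perturbation %+g pushes `%s` outside the model's validity range.",
        d, parameter), class = "vasckill_domain_error")
    }
    p$fkill_m * kill_factor(p$bvf, p$rb_um / p$L_um)
  }
  S <- if (method == "forward") {
    (y_at(perturbation) - y0) / y0 / perturbation
  } else {
    (y_at(perturbation) - y_at(-perturbation)) / (2 * perturbation * y0)
  }
  tibble(parameter = parameter, perturbation = perturbation, S = S)
}

#' Rank parameters by mean absolute sensitivity
#'
#' Computes [sensitivity_coefficient()] for each parameter over a grid of
#' perturbation sizes and orders parameters by descending mean \eqn{|S|}.
#' The default grid uses positive forward perturbations of 1%, 10% and
#' 25%: with symmetric \eqn{\pm\delta} grids the coefficients of `rb_um`
#' and `L_um` — which enter the model only through \eqn{r_b/L} — are
#' near-mirror images and their ordering would reflect the sign convention
#' rather than the model.
#'
#' @param reference A [model_params()] object.
#' @param parameters Character vector of parameters to rank (default all
#'   four).
#' @param deltas Non-empty numeric vector of relative perturbations
#'   (default `c(0.01, 0.1, 0.25)`).
#' @param method Passed to [sensitivity_coefficient()].
#' @return A tibble with columns `parameter` and `mean_abs_S`, sorted by
#'   descending `mean_abs_S`; exact ties are broken alphabetically with a
#'   message. The per-delta coefficients are attached as attribute
#'   `"coefficients"` (a tibble of `parameter`, `perturbation`, `S`).
#' @examples
#' p <- model_params(0.038, 5, 40, 0.25)
#' sensitivity_ranking(p)
#' @export
sensitivity_ranking <- function(reference,
                                parameters = SENSITIVITY_PARAMS,
                                deltas = c(0.01, 0.1, 0.25),
                                method = "forward") {
  if (length(deltas) == 0L) {
    abort("`deltas` must be non-empty.", class = "vasckill_domain_error")
  }
  parameters <- match.arg(parameters, SENSITIVITY_PARAMS,
                          several.ok = TRUE)
  coefs <- purrr::map_dfr(parameters, function(pp) {
    purrr::map_dfr(deltas, function(d) {
      sensitivity_coefficient(reference, pp, d, method = method)
    })
  })
  ranking <- coefs |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(mean_abs_S = mean(abs(.data$S)), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_abs_S), .data$parameter)
  if (anyDuplicated(ranking$mean_abs_S) > 0L) {
    inform("Tied mean |S| values; tie broken alphabetically.")
  }
  attr(ranking, "coefficients") <- coefs
  ranking
}
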