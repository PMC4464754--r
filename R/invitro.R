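# In-vitro dose-response: four-parameter logistic (4PL/Hill) IC50 fits,
# fold difference between lines, and the sensitive/resistant kill ratio
# used to put both lines' in-vivo kill data on one scale.

# 4PL viability as a function of concentration (nM)
hill_4pl <- function(conc, top, bottom, ic50, slope) {
  bottom + (top - bottom) / (1 + (conc / ic50)^slope)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of viability against concentration with the standard
#' 4PL (Hill) model
#' \deqn{v(c) = bottom + \frac{top - bottom}{1 + (c / IC_{50})^{h}},}
#' estimating `top`, `bottom`, the Hill slope `h` and the IC50 — the
#' concentration at half-maximal inhibition between the fitted plateaus.
#' Fitting is by bounded Levenberg-Marquardt (`minpack.lm::nls.lm`) on
#' log-IC50.
#'
#' @param curve Data frame with columns `concentration_nM` (positive,
#'   ascending) and `viability_fraction` (in \[0, 1\]); at least 4 points
#'   spanning a decline.
#' @return An object of class `ic50_fit` with fields `ic50_nM`,
#'   `hill_slope`, `top`, `bottom`, `converged`, `residuals`, `fitted`,
#'   `data`, and `message` (diagnostics when not converged). Degenerate
#'   input (no decline) yields `converged = FALSE`, never an opaque
#'   failure.
#' @examples
#' curve <- generate_dose_response(synthetic_config(dose_noise_sd = 0))
#' fit <- fit_hill_ic50(dplyr::filter(curve, line == "sensitive"))
#' fit$ic50_nM
#' @export
fit_hill_ic50 <- function(curve) {
  check_columns(curve, c("concentration_nM", "viability_fraction"), "curve")
  conc <- curve$concentration_nM
  v <- curve$viability_fraction
  if (length(conc) < 4L) {
    abort("At least 4 dose-response points are required.",
          class = "vasckill_validation_error")
  }
  if (any(conc <= 0)) {
    abort("Concentrations must be strictly positive.",
          class = "vasckill_validation_error")
  }
  fail <- function(msg) {
    structure(list(ic50_nM = NA_real_, hill_slope = NA_real_,
                   top = NA_real_, bottom = NA_real_, converged = FALSE,
                   residuals = rep(NA_real_, length(v)),
                   fitted = rep(NA_real_, length(v)),
                   data = as_tibble(curve), message = msg),
              class = "ic50_fit")
  }
  if (diff(range(v)) < 1e-8) {
    return(fail("viability is constant across concentrations; no decline to fit"))
  }
  # start values: plateaus from data extremes, IC50 near the half-decline
  top0 <- max(v)
  bot0 <- min(v)
  half <- (top0 + bot0) / 2
  ic0 <- exp(stats::approx(v, log(conc), xout = half, ties = mean)$y)
  if (!is.finite(ic0)) ic0 <- exp(mean(log(range(conc))))
  lc <- log(conc)
  resid_fn <- function(par) {
    v - (par[["bottom"]] + (par[["top"]] - par[["bottom"]]) /
           (1 + exp(par[["slope"]] * (lc - par[["lic50"]]))))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(top = top0, bottom = bot0, lic50 = log(ic0), slope = 1),
      lower = c(top = 0, bottom = 0, lic50 = log(min(conc)) - 10,
                slope = 0.1),
      upper = c(top = 1.5, bottom = 1, lic50 = log(max(conc)) + 10,
                slope = 10),
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) conditionMessage(e)
  )
  if (is.character(fit)) return(fail(fit))
  # info codes 1-3 signal convergence in minpack's termination taxonomy
  if (!fit$info %in% 1:3) {
    return(fail(sprintf("optimizer did not converge (info %d): %s",
                        fit$info, fit$message)))
  }
  cf <- fit$par
  if (cf[["bottom"]] > cf[["top"]]) {
    return(fail("fitted bottom exceeds top; curve is not a decline"))
  }
  res <- resid_fn(cf)
  structure(
    list(ic50_nM = exp(cf[["lic50"]]), hill_slope = cf[["slope"]],
         top = cf[["top"]], bottom = cf[["bottom"]], converged = TRUE,
         residuals = as.numeric(res), fitted = as.numeric(v - res),
         data = as_tibble(curve), message = NULL),
    class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat("<ic50_fit>\n")
  if (x$converged) {
    cat(sprintf("  IC50   : %.4g nM\n  slope  : %.3g\n  top    : %.3g\n  bottom : %.3g\n",
                x$ic50_nM, x$hill_slope, x$top, x$bottom))
  } else {
    cat("  did not converge:", x$message, "\n")
  }
  invisible(x)
}

#' @method tidy ic50_fit
#' @export
tidy.ic50_fit <- function(x, ...) {
  tibble(
    term = c("ic50_nM", "hill_slope", "top", "bottom"),
    estimate = c(x$ic50_nM, x$hill_slope, x$top, x$bottom)
  )
}

#' @method glance ic50_fit
#' @export
glance.ic50_fit <- function(x, ...) {
  tibble(
    ic50_nM = x$ic50_nM,
    hill_slope = x$hill_slope,
    converged = x$converged,
    n = nrow(x$data),
    rss = if (x$converged) sum(x$residuals^2) else NA_real_
  )
}

#' IC50 fold difference between two cell lines
#'
#' The differential in drug response: ratio of the larger (resistant) IC50
#' to the smaller (sensitive) one, so the result is >= 1 by construction.
#'
#' @param ic50_resistant,ic50_sensitive IC50 values in nM, > 0.
#' @return A one-row tibble with `fold` (raw ratio) and `fold_nearest`
#'   (nearest integer).
#' @examples
#' fold_difference(46.2, 3.5) # ~ 13x
#' @export
fold_difference <- function(ic50_resistant, ic50_sensitive) {
  check_number(ic50_resistant, "ic50_resistant", 0, Inf,
               allow_boundary = FALSE)
  check_number(ic50_sensitive, "ic50_sensitive", 0, Inf,
               allow_boundary = FALSE)
  fold <- max(ic50_resistant, ic50_sensitive) /
    min(ic50_resistant, ic50_sensitive)
  tibble(fold = fold, fold_nearest = as.integer(round(fold)))
}

#' In-vitro kill ratio between sensitive and resistant lines
#'
#' Ratio of the dead-cell fraction of the drug-sensitive line to that of
#' the drug-resistant line at the matched drug concentration; used to
#' rescale the resistant line's in-vivo kill data onto the sensitive
#' line's scale before the pooled calibration (see [rescale_resistant()]).
#' The study-level default when no measurements are available is 3.5.
#'
#' @param dead_fraction_sensitive,dead_fraction_resistant Dead-cell
#'   fractions in \[0, 1\]; the resistant fraction must be positive.
#' @return The ratio, a single number.
#' @examples
#' invitro_kill_ratio(0.35, 0.10)
#' @export
invitro_kill_ratio <- function(dead_fraction_sensitive,
                               dead_fraction_resistant) {
  check_number(dead_fraction_sensitive, "dead_fraction_sensitive", 0, 1)
  if (!is.numeric(dead_fraction_resistant) ||
      length(dead_fraction_resistant) != 1L ||
      !is.finite(dead_fraction_resistant) || dead_fraction_resistant <= 0) {
    abort(paste("`dead_fraction_resistant` must be > 0; with no measurement,",
                "use the configured default ratio (3.5)."),
          class = "vasckill_validation_error")
  }
  dead_fraction_sensitive / dead_fraction_resistant
}
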