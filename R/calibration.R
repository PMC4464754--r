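# Calibration: rescale resistant-line kill data by the in-vitro ratio, fit
# the closed-form kill model to (BVF, dead fraction) points by bounded
# nonlinear least squares, and report R^2.
#
# The model is linear in fkill_m, so the fit profiles it out in closed form
# (variable projection): for each candidate rb_over_L the optimal fkill_m is
# sum(y * g) / sum(g^2) with g the dimensionless kill factor, clamped to
# [0, 1]. The remaining 1-D bounded problem in log(rb_over_L) is solved by
# L-BFGS-B from multiple starts. This makes noiseless recovery exact and the
# fitted fkill_m exactly proportional to the data scale.

#' Rescale the drug-resistant line's kill data
#'
#' Multiplies the resistant-line dead fractions by the in-vitro
#' sensitive/resistant kill ratio so both lines' points share the
#' sensitive line's cell-intrinsic scale; sensitive points are untouched.
#' A dataset can only be rescaled once.
#'
#' @param data Kill dataset: data frame with columns `line`, `bvf`,
#'   `dead_fraction` (see [read_kill_data()]).
#' @param factor Positive rescale factor; the study-level default is 3.5.
#' @return The dataset with resistant `dead_fraction` multiplied by
#'   `factor` and attribute `rescaled = TRUE`. Rescaled values above 1 are
#'   allowed but reported via a message.
#' @examples
#' d <- tibble::tibble(line = c("sensitive", "resistant"),
#'                     bvf = c(0.03, 0.04), dead_fraction = c(0.1, 0.047))
#' rescale_resistant(d, 3.5)
#' @export
rescale_resistant <- function(data, factor = 3.5) {
  check_columns(data, c("line", "bvf", "dead_fraction"), "data")
  check_number(factor, "factor", 0, Inf, allow_boundary = FALSE)
  if (isTRUE(attr(data, "rescaled"))) {
    abort("`data` has already been rescaled.",
          class = "vasckill_validation_error")
  }
  out <- data |>
    dplyr::mutate(dead_fraction = ifelse(.data$line == "resistant",
                                         .data$dead_fraction * factor,
                                         .data$dead_fraction))
  n_over <- sum(out$dead_fraction > 1)
  if (n_over > 0L) {
    inform(sprintf("%d rescaled dead fraction(s) exceed 1.", n_over))
  }
  out <- as_tibble(out)
  attr(out, "rescaled") <- TRUE
  out
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} with the total sum of squares taken
#' about the observed mean; can be negative for a fit worse than the mean.
#'
#' @param observed,predicted Equal-length numeric vectors, length >= 2;
#'   the observed values must vary.
#' @return A single number <= 1.
#' @examples
#' r_squared(c(1, 2, 3), c(1.1, 1.9, 3.2))
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L) {
    abort("`observed` and `predicted` must be equal-length vectors (n >= 2).",
          class = "vasckill_validation_error")
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    abort("`observed` has zero variance; R^2 is undefined.",
          class = "vasckill_validation_error")
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

# profile fkill_m for a given rb_over_L: closed-form linear LS. Only the
# (scale-invariant) non-negativity clamp is applied here; the upper bound
# is enforced afterwards by a constrained re-solve when it binds.
profiled_fkill_m <- function(rho, bvf, y) {
  g <- kill_factor(bvf, rho)
  fm <- sum(y * g) / sum(g * g)
  max(fm, 0)
}

#' Calibrate the kill model to per-section kill data
#'
#' Fits the closed-form kill fraction to observed (BVF, dead fraction)
#' points by bounded least squares, estimating the in-vitro kill fraction
#' \eqn{f^{M}_{kill}} and the scaled vessel radius \eqn{r_b/L}. Because
#' the model is linear in \eqn{f^{M}_{kill}}, that parameter is profiled
#' out in closed form and the remaining one-dimensional problem in
#' \eqn{\log(r_b/L)} is solved from multiple starts (the surface can be
#' flat at small \eqn{r_b/L}); the best restart wins. Deterministic for a
#' given `seed`.
#'
#' @param data Kill dataset with columns `bvf` (in (0, 1), not all equal)
#'   and `dead_fraction`; typically the output of [rescale_resistant()].
#' @param init Optional list with starting values `fkill_m` and
#'   `rb_over_L` (the first restart; `fkill_m` is only advisory since the
#'   parameter is profiled).
#' @param bounds List with `rb_over_L` = c(lower, upper) (default
#'   \code{c(1e-3, 2)}) and `fkill_m` = c(0, 1).
#' @param multistart Number of restarts (default 10); starts beyond `init`
#'   are log-uniform in the `rb_over_L` bounds.
#' @param seed Integer seed making the restart draws reproducible.
#' @return A `kill_fit` object: estimates `fkill_m_hat` and
#'   `rb_over_L_hat`, `r_squared`, per-point `residuals` and `fitted`,
#'   `iterations`, `converged`, the 2x2 `covariance` estimate of the
#'   parameters, the `data`, and per-restart diagnostics in `restarts`.
#' @examples
#' sim <- generate_kill_dataset(synthetic_config(kill_noise_sd = 0))
#' fit <- fit_kill_model(rescale_resistant(sim$data, 3.5), seed = 1)
#' glance(fit)
#' @export
fit_kill_model <- function(data,
                           init = list(fkill_m = 0.2, rb_over_L = 0.1),
                           bounds = list(rb_over_L = c(1e-3, 2),
                                         fkill_m = c(0, 1)),
                           multistart = 10,
                           seed = 1) {
  check_columns(data, c("bvf", "dead_fraction"), "data")
  bvf <- data$bvf
  y <- data$dead_fraction
  if (length(bvf) < 3L) {
    abort("At least 3 points are required to calibrate.",
          class = "vasckill_validation_error")
  }
  if (any(bvf <= 0 | bvf >= 1)) {
    abort("`bvf` values must lie strictly inside (0, 1).",
          class = "vasckill_validation_error")
  }
  if (diff(range(bvf)) < 1e-12) {
    abort("All `bvf` values are identical; rb_over_L is not identifiable.",
          class = "vasckill_identifiability_error")
  }
  lb <- log(bounds$rb_over_L[1])
  ub <- log(bounds$rb_over_L[2])
  # optimize on unit-scale observations so the optimizer's path, and hence
  # rb_over_L_hat, is invariant to the absolute scale of the data (making
  # the fitted fkill_m exactly proportional to it)
  y_scale <- max(abs(y))
  if (y_scale == 0) {
    abort("All dead fractions are zero; nothing to calibrate.",
          class = "vasckill_validation_error")
  }
  yn <- y / y_scale
  sse <- function(lrho) {
    rho <- exp(lrho)
    fm <- profiled_fkill_m(rho, bvf, yn)
    r <- yn - fm * kill_factor(bvf, rho)
    sum(r * r)
  }
  starts <- with_preserved_seed(seed, {
    c(log(init$rb_over_L),
      if (multistart > 1) runif(multistart - 1, lb, ub))
  })
  starts <- pmin(pmax(starts, lb), ub)
  restarts <- purrr::map_dfr(seq_along(starts), function(i) {
    res <- tryCatch(
      optim(starts[i], sse, method = "L-BFGS-B", lower = lb, upper = ub,
            control = list(factr = 1e4)),
      error = function(e) NULL
    )
    if (is.null(res)) {
      tibble(start_rb_over_L = exp(starts[i]), rb_over_L = NA_real_,
             sse = Inf, iterations = NA_integer_, converged = FALSE)
    } else {
      tibble(start_rb_over_L = exp(starts[i]), rb_over_L = exp(res$par),
             sse = res$value * y_scale^2,
             iterations = res$counts[["function"]],
             converged = res$convergence == 0)
    }
  })
  ok <- restarts$converged & is.finite(restarts$sse)
  if (!any(ok)) {
    return(structure(
      list(fkill_m_hat = NA_real_, rb_over_L_hat = NA_real_,
           r_squared = NA_real_, residuals = rep(NA_real_, length(y)),
           fitted = rep(NA_real_, length(y)), iterations = NA_integer_,
           converged = FALSE, covariance = NULL,
           data = as_tibble(data), restarts = restarts),
      class = "kill_fit"))
  }
  best <- which(restarts$sse == min(restarts$sse[ok]) & ok)[1]
  rho_hat <- restarts$rb_over_L[best]
  # Brent polish on a bracket around the winner: x-tolerance based, so the
  # result does not depend on the absolute scale of the residuals
  bracket <- c(max(rho_hat / 2, bounds$rb_over_L[1]),
               min(rho_hat * 2, bounds$rb_over_L[2]))
  polish <- stats::optimize(function(r) sse(log(r)),
                            interval = bracket, tol = 1e-10)
  if (polish$objective <= sse(log(rho_hat))) rho_hat <- polish$minimum
  fm_hat <- y_scale * profiled_fkill_m(rho_hat, bvf, yn)
  fm_max <- bounds$fkill_m[2]
  if (fm_hat > fm_max) {
    # the in-vitro kill fraction bound binds: re-solve for rb_over_L with
    # fkill_m pinned to the bound
    sse_fixed <- function(lrho) {
      sum((y - fm_max * kill_factor(bvf, exp(lrho)))^2)
    }
    con <- stats::optimize(function(r) sse_fixed(log(r)),
                           interval = bounds$rb_over_L, tol = 1e-10)
    rho_hat <- con$minimum
    fm_hat <- fm_max
  }
  pred <- fm_hat * kill_factor(bvf, rho_hat)
  res <- y - pred
  covariance <- kill_fit_covariance(fm_hat, rho_hat, bvf, res)
  structure(
    list(fkill_m_hat = fm_hat, rb_over_L_hat = rho_hat,
         r_squared = r_squared(y, pred), residuals = res, fitted = pred,
         iterations = restarts$iterations[best], converged = TRUE,
         covariance = covariance, data = as_tibble(data),
         restarts = restarts),
    class = "kill_fit")
}

# Gauss-Newton covariance: sigma^2 (J'J)^-1 with a forward-difference
# Jacobian in (fkill_m, rb_over_L); NULL when the normal matrix is singular.
kill_fit_covariance <- function(fm, rho, bvf, res) {
  n <- length(bvf)
  if (n <= 2L) return(NULL)
  g <- kill_factor(bvf, rho)
  h <- rho * 1e-6
  dg <- (kill_factor(bvf, rho + h) - g) / h
  J <- cbind(fkill_m = g, rb_over_L = fm * dg)
  JtJ <- crossprod(J)
  s2 <- sum(res^2) / (n - 2L)
  inv <- tryCatch(solve(JtJ), error = function(e) NULL)
  if (is.null(inv)) return(NULL)
  s2 * inv
}

#' @export
print.kill_fit <- function(x, ...) {
  cat("<kill_fit>\n")
  if (x$converged) {
    cat(sprintf("  fkill^M   : %.4g\n  r_b / L   : %.4g\n  R-squared : %.4g\n  n points  : %d\n",
                x$fkill_m_hat, x$rb_over_L_hat, x$r_squared, nrow(x$data)))
  } else {
    cat("  all restarts failed; see $restarts\n")
  }
  invisible(x)
}

#' @describeIn fit_kill_model One row per parameter with estimate and
#'   standard error (from the Gauss-Newton covariance).
#' @param x A `kill_fit` object.
#' @param ... Unused.
#' @method tidy kill_fit
#' @export
tidy.kill_fit <- function(x, ...) {
  se <- if (is.null(x$covariance)) c(NA_real_, NA_real_)
        else sqrt(diag(x$covariance))
  tibble(
    term = c("fkill_m", "rb_over_L"),
    estimate = c(x$fkill_m_hat, x$rb_over_L_hat),
    std.error = as.numeric(se)
  )
}

#' @describeIn fit_kill_model One-row model-level summary.
#' @method glance kill_fit
#' @export
glance.kill_fit <- function(x, ...) {
  tibble(
    fkill_m_hat = x$fkill_m_hat,
    rb_over_L_hat = x$rb_over_L_hat,
    r.squared = x$r_squared,
    rss = sum(x$residuals^2),
    n = nrow(x$data),
    converged = x$converged
  )
}

#' @describeIn fit_kill_model The data with `.fitted` and `.resid` columns.
#' @method augment kill_fit
#' @export
augment.kill_fit <- function(x, ...) {
  dplyr::mutate(x$data, .fitted = x$fitted, .resid = x$residuals)
}
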