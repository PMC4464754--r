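# Core diffusion-uptake model: concentration profile around a vessel and the
# closed-form fraction of tumor volume killed.
#
# The steady-state drug balance around a single straight cylindrical vessel,
# with radial coordinate scaled by the penetration distance L = sqrt(D/lambda),
# is (1/r) d/dr (r dsigma/dr) = sigma. With sigma = sigma0 at the vessel wall
# and decay far from it the solution is sigma/sigma0 = K0(r)/K0(rb), where K0
# is the modified Bessel function of the second kind. All Bessel evaluations
# use the exponentially scaled forms; with both arguments >= rb the residual
# factor exp(rb - r) <= 1 so no overflow/underflow branch is needed.

# guard above which the vanishing-annulus limit (f_kill -> fkill_m) is returned
.BVF_LIMIT_GUARD <- 1 - 1e-6

#' Scaled drug concentration around a vessel
#'
#' Evaluates the normalized steady-state concentration
#' \eqn{\sigma/\sigma_0 = K_0(\hat r) / K_0(\hat r_b)} at scaled radius
#' \eqn{\hat r = r/L}, where \eqn{\hat r_b = r_b/L} is the scaled vessel
#' radius. The profile equals 1 at the vessel wall and decays monotonically
#' with distance.
#'
#' @param r_scaled Numeric vector of scaled radii, all `>= rb_over_L`.
#' @param rb_over_L Scaled vessel radius, > 0.
#' @return Numeric vector of normalized concentrations in (0, 1].
#' @examples
#' scaled_concentration(c(0.068, 0.1, 0.3), rb_over_L = 0.068)
#' @seealso [concentration_profile()] for a tidy profile table.
#' @export
scaled_concentration <- function(r_scaled, rb_over_L) {
  check_number(rb_over_L, "rb_over_L", 0, Inf, allow_boundary = FALSE)
  if (!is.numeric(r_scaled) || length(r_scaled) == 0L ||
      any(!is.finite(r_scaled))) {
    abort("`r_scaled` must be a non-empty finite numeric vector.",
          class = "vasckill_domain_error")
  }
  if (any(r_scaled < rb_over_L)) {
    bad <- min(r_scaled)
    abort(sprintf(
      "`r_scaled` contains %g, below the vessel wall `rb_over_L` = %g.",
      bad, rb_over_L), class = "vasckill_domain_error")
  }
  exp(rb_over_L - r_scaled) *
    besselK(r_scaled, 0, expon.scaled = TRUE) /
    besselK(rb_over_L, 0, expon.scaled = TRUE)
}

#' Concentration profile table
#'
#' Tabulates [scaled_concentration()] on a radius grid from the vessel wall
#' outward, as a tibble ready for plotting.
#'
#' @param rb_over_L Scaled vessel radius, > 0.
#' @param r_max Outer scaled radius of the grid (default 10 penetration
#'   distances).
#' @param n Number of grid points.
#' @param sigma0 Reference concentration at the vessel wall (arbitrary
#'   units); carried as a column for convenience.
#' @return A tibble with columns `scaled_radius`, `concentration` (the
#'   normalized \eqn{\sigma/\sigma_0}) and `sigma0`.
#' @examples
#' concentration_profile(0.068, r_max = 2, n = 50)
#' @export
concentration_profile <- function(rb_over_L, r_max = 10, n = 200,
                                  sigma0 = 1) {
  check_number(r_max, "r_max", rb_over_L, Inf, allow_boundary = FALSE)
  r <- seq(rb_over_L, r_max, length.out = n)
  tibble(
    scaled_radius = r,
    concentration = scaled_concentration(r, rb_over_L),
    sigma0 = sigma0
  )
}

# complement 1 - x K1(x), the stable quantity behind the annulus integral:
# int_a^t x K0(x) dx = (1 - t K1(t)) - (1 - a K1(a)). Direct evaluation
# cancels catastrophically for small x, where x K1(x) -> 1; the leading
# series takes over below 1e-4 (relative error O(x^2)).
xk1_complement <- function(x) {
  out <- numeric(length(x))
  small <- x < 1e-4
  xs <- x[small]
  out[small] <- -(xs^2 / 2) * (log(xs / 2) + 0.57721566490153286 - 0.5)
  xl <- x[!small]
  out[!small] <- 1 - xl * besselK(xl, 1, expon.scaled = TRUE) * exp(-xl)
  out
}

# dimensionless part of the closed-form kill fraction, vectorized over bvf
# and rb_over_L; the full model is fkill_m times this factor.
kill_factor <- function(bvf, rb_over_L) {
  stopifnot(length(bvf) == length(rb_over_L) || length(bvf) == 1L ||
              length(rb_over_L) == 1L)
  n <- max(length(bvf), length(rb_over_L))
  bvf <- rep_len(bvf, n)
  a <- rep_len(rb_over_L, n)
  out <- numeric(n)
  lim <- bvf > .BVF_LIMIT_GUARD
  out[lim] <- 1
  if (any(!lim)) {
    bv <- bvf[!lim]
    ab <- a[!lim]
    s <- sqrt(bv)
    at <- ab / s # scaled tissue radius
    val <- numeric(length(ab))
    # small vessel radius: the two x K1(x) terms both approach 1 and their
    # difference cancels in doubles; evaluate via the complements instead
    sm <- ab < 0.05
    if (any(sm)) {
      val[sm] <- 2 * bv[sm] *
        (xk1_complement(at[sm]) - xk1_complement(ab[sm])) /
        (ab[sm]^2 * (1 - bv[sm]) * besselK(ab[sm], 0))
    }
    if (any(!sm)) {
      num <- 2 * s[!sm] * besselK(ab[!sm], 1, expon.scaled = TRUE) -
        2 * besselK(at[!sm], 1, expon.scaled = TRUE) *
          exp(ab[!sm] - at[!sm])
      den <- s[!sm] * ab[!sm] *
        besselK(ab[!sm], 0, expon.scaled = TRUE) * (1 - bv[!sm])
      val[!sm] <- bv[!sm] * num / den
    }
    if (any(!is.finite(val))) {
      abort("Bessel evaluation of the kill factor produced a non-finite value.",
            class = "vasckill_numeric_error")
    }
    out[!lim] <- val
  }
  out
}

#' Closed-form fraction of tumor volume killed
#'
#' Evaluates the model's central quantity: the fraction of tumor volume
#' killed by one drug administration,
#' \deqn{f_{kill} = f^{M}_{kill}\; BVF\;
#'   \frac{2\sqrt{BVF}\,K_1(\hat r_b) - 2 K_1(\hat r_b/\sqrt{BVF})}
#'        {\sqrt{BVF}\,\hat r_b\,K_0(\hat r_b)\,(1 - BVF)},}
#' with \eqn{\hat r_b = r_b / L}. This is the area-weighted average of the
#' normalized concentration profile over the tissue annulus
#' \eqn{[\hat r_b, \hat r_b/\sqrt{BVF}]}, scaled by the in-vitro kill
#' fraction. For `bvf` within 1e-6 of 1 the analytic vanishing-annulus limit
#' `fkill_m` is returned.
#'
#' @param params A [model_params()] object.
#' @return The kill fraction, a number in \[0, `fkill_m`\].
#' @examples
#' kill_fraction(model_params(0.038, 5, 40, 0.25))
#' @seealso [kill_fraction_oracle()] for the quadrature cross-check,
#'   [predict_curve()] for evaluation along a BVF grid.
#' @export
kill_fraction <- function(params) {
  if (!inherits(params, "model_params")) {
    abort("`params` must be a model_params object.",
          class = "vasckill_validation_error")
  }
  params$fkill_m * kill_factor(params$bvf, params$rb_over_L)
}

#' Quadrature oracle for the kill fraction
#'
#' Recomputes the kill fraction without the closed form: the concentration
#' profile is averaged over the tissue annulus by adaptive quadrature,
#' \deqn{f_{kill} = f^{M}_{kill} \frac{2}{\hat r_t^2 - \hat r_b^2}
#'   \int_{\hat r_b}^{\hat r_t} x \frac{K_0(x)}{K_0(\hat r_b)}\,dx,}
#' with \eqn{\hat r_t = \hat r_b/\sqrt{BVF}}. Used as an independent check
#' on [kill_fraction()]; the two agree to better than 1e-6 relative over
#' the model's working range.
#'
#' @param params A [model_params()] object.
#' @param tol Relative tolerance passed to the adaptive quadrature.
#' @return The kill fraction.
#' @examples
#' p <- model_params(0.04, 5, 73.5, 0.25)
#' kill_fraction_oracle(p) - kill_fraction(p)
#' @export
kill_fraction_oracle <- function(params, tol = 1e-10) {
  if (!inherits(params, "model_params")) {
    abort("`params` must be a model_params object.",
          class = "vasckill_validation_error")
  }
  check_number(tol, "tol", 0, Inf, allow_boundary = FALSE)
  if (params$fkill_m == 0) return(0)
  if (params$bvf > .BVF_LIMIT_GUARD) return(params$fkill_m)
  a <- params$rb_over_L
  rt <- a / sqrt(params$bvf)
  k0a <- besselK(a, 0, expon.scaled = TRUE)
  quad <- tryCatch(
    integrate(function(x) {
      x * besselK(x, 0, expon.scaled = TRUE) * exp(a - x) / k0a
    }, lower = a, upper = rt, rel.tol = tol, subdivisions = 500L),
    error = function(e) {
      abort(paste0("Quadrature failed to converge: ", conditionMessage(e)),
            class = "vasckill_numeric_error")
    }
  )
  params$fkill_m * 2 / (rt^2 - a^2) * quad$value
}

#' Predicted kill fraction along a BVF grid
#'
#' Evaluates the closed-form kill fraction at each blood volume fraction in
#' `bvf_grid`, holding \eqn{f^{M}_{kill}} and \eqn{r_b/L} fixed; this is
#' the model curve that calibrated fits are drawn against.
#'
#' @param fkill_m In-vitro kill fraction in \[0, 1\].
#' @param rb_over_L Scaled vessel radius, > 0.
#' @param bvf_grid Sorted vector of blood volume fractions in (0, 1).
#' @return A tibble with columns `bvf` and `f_kill`; `f_kill` is strictly
#'   increasing along the grid (vascularization always helps delivery).
#' @examples
#' predict_curve(0.25, 0.068, seq(0.01, 0.2, by = 0.01))
#' @export
predict_curve <- function(fkill_m, rb_over_L, bvf_grid) {
  check_number(fkill_m, "fkill_m", 0, 1)
  check_number(rb_over_L, "rb_over_L", 0, Inf, allow_boundary = FALSE)
  if (length(bvf_grid) == 0L || any(!is.finite(bvf_grid)) ||
      any(bvf_grid <= 0) || any(bvf_grid >= 1)) {
    abort("`bvf_grid` values must lie strictly inside (0, 1).",
          class = "vasckill_domain_error")
  }
  if (is.unsorted(bvf_grid)) {
    abort("`bvf_grid` must be sorted increasing.",
          class = "vasckill_domain_error")
  }
  tibble(
    bvf = as.numeric(bvf_grid),
    f_kill = fkill_m * kill_factor(bvf_grid, rb_over_L)
  )
}
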