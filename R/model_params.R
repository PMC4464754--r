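#' Tumor-specific model parameters
#'
#' Bundle the four measurable parameters that drive the kill-fraction model:
#' the blood volume fraction (BVF), the mean blood vessel radius \eqn{r_b}
#' (\eqn{\mu m}), the drug diffusion penetration distance \eqn{L}
#' (\eqn{\mu m}), and the maximal in-vitro kill fraction
#' \eqn{f^{M}_{kill}} measured in monolayer culture at the matched drug
#' concentration. Optionally the drug diffusivity \eqn{D} (\eqn{\mu m^2/s})
#' and the cellular uptake rate \eqn{\lambda} (1/s) may be given, in which
#' case they must be consistent with \eqn{L = \sqrt{D/\lambda}}.
#'
#' All lengths are in micrometres and all fractions on \[0, 1\]; percentages
#' are accepted only at I/O boundaries (see [read_kill_data()]).
#'
#' @param bvf Blood volume fraction, in (0, 1).
#' @param rb_um Mean vessel radius in \eqn{\mu m}, > 0.
#' @param L_um Diffusion penetration distance in \eqn{\mu m}, > 0.
#' @param fkill_m In-vitro kill fraction in \[0, 1\].
#' @param D_um2_s,lambda_per_s Optional diffusivity and uptake rate; if both
#'   are supplied, `sqrt(D_um2_s / lambda_per_s)` must equal `L_um` to a
#'   relative tolerance of 1e-9.
#'
#' @return An object of class `model_params`: a named list with the fields
#'   above plus the derived dimensionless ratio `rb_over_L`.
#'
#' @examples
#' p <- model_params(bvf = 0.038, rb_um = 5, L_um = 40, fkill_m = 0.25)
#' p$rb_over_L
#' kill_fraction(p)
#' @export
model_params <- function(bvf, rb_um, L_um, fkill_m,
                         D_um2_s = NULL, lambda_per_s = NULL) {
  check_number(bvf, "bvf", 0, 1, allow_boundary = FALSE)
  check_number(rb_um, "rb_um", 0, Inf, allow_boundary = FALSE)
  check_number(L_um, "L_um", 0, Inf, allow_boundary = FALSE)
  check_number(fkill_m, "fkill_m", 0, 1)
  if (!is.null(D_um2_s) && !is.null(lambda_per_s)) {
    check_number(D_um2_s, "D_um2_s", 0, Inf, allow_boundary = FALSE)
    check_number(lambda_per_s, "lambda_per_s", 0, Inf, allow_boundary = FALSE)
    L_implied <- sqrt(D_um2_s / lambda_per_s)
    if (abs(L_implied - L_um) > 1e-9 * L_um) {
      abort(sprintf(
        "`L_um` (%g) is inconsistent with sqrt(D/lambda) = %g.",
        L_um, L_implied), class = "vasckill_validation_error")
    }
  }
  structure(
    list(bvf = bvf, rb_um = rb_um, L_um = L_um, fkill_m = fkill_m,
         D_um2_s = D_um2_s, lambda_per_s = lambda_per_s,
         rb_over_L = rb_um / L_um),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  BVF      : %.4g\n", x$bvf))
  cat(sprintf("  r_b      : %.4g um\n", x$rb_um))
  cat(sprintf("  L        : %.4g um\n", x$L_um))
  cat(sprintf("  r_b / L  : %.4g\n", x$rb_over_L))
  cat(sprintf("  fkill^M  : %.4g\n", x$fkill_m))
  invisible(x)
}

#' Krogh-type tissue cylinder geometry
#'
#' Each vessel of scaled radius \eqn{\hat r_b = r_b / L} serves a coaxial
#' tissue cylinder whose outer scaled radius follows from the blood volume
#' fraction: \eqn{\hat r_t = \hat r_b / \sqrt{BVF}} (so that
#' \eqn{BVF = (r_b/r_t)^2}).
#'
#' @param bvf Blood volume fraction in (0, 1).
#' @param rb_over_L Scaled vessel radius \eqn{r_b/L}, > 0.
#' @return A one-row tibble with columns `rb_scaled` and `rt_scaled`.
#' @examples
#' tissue_geometry(0.04, 0.068)
#' @export
tissue_geometry <- function(bvf, rb_over_L) {
  check_number(bvf, "bvf", 0, 1, allow_boundary = FALSE)
  check_number(rb_over_L, "rb_over_L", 0, Inf, allow_boundary = FALSE)
  tibble(rb_scaled = rb_over_L, rt_scaled = rb_over_L / sqrt(bvf))
}
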