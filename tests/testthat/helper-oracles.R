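# Independent numerical oracles used across the suite. These deliberately
# avoid the closed-form Bessel expression they are checking.

# Finite-difference boundary-value solve of the radial diffusion-uptake
# equation (1/r)(r sigma')' = sigma on [rb, r_out], with sigma(rb) = 1 and
# sigma(r_out) matching the decaying K0 profile. Solved in log-radius
# (t = log r), where the equation becomes sigma_tt = exp(2 t) sigma and a
# uniform grid resolves the steep near-vessel region. Returns an
# interpolant over the interior.
fd_concentration_solver <- function(rb, r_out = 20, n = 20000L) {
  t0 <- log(rb)
  t1 <- log(r_out)
  h <- (t1 - t0) / n
  tt <- seq(t0, t1, length.out = n + 1L)
  sig_left <- 1
  sig_right <- besselK(r_out, 0) / besselK(rb, 0)
  # interior unknowns i = 2..n: (s[i-1] - 2 s[i] + s[i+1]) / h^2 = e^{2t} s[i]
  m <- n - 1L
  diag_main <- -2 / h^2 - exp(2 * tt[2:n])
  rhs <- numeric(m)
  rhs[1] <- -sig_left / h^2
  rhs[m] <- -sig_right / h^2
  A <- Matrix::bandSparse(m, m, k = c(-1, 0, 1),
                          diagonals = list(rep(1 / h^2, m - 1L), diag_main,
                                           rep(1 / h^2, m - 1L)))
  sol <- as.numeric(Matrix::solve(A, rhs))
  sig <- c(sig_left, sol, sig_right)
  function(r) stats::spline(tt, sig, xout = log(r))$y
}

# High-order central difference derivative (4th order, step h)
central_diff4 <- function(f, x, h) {
  (8 * (f(x + h) - f(x - h)) - (f(x + 2 * h) - f(x - 2 * h))) / (12 * h)
}

ref_params <- function(bvf = 0.038, rb = 5, L = 40, fm = 0.25) {
  model_params(bvf = bvf, rb_um = rb, L_um = L, fkill_m = fm)
}

# closed-form mean and sd of a normal truncated to [lower, upper]
# (the generators' sampling distribution for stain fractions and BVF)
truncnorm_moments <- function(mean, sd, lower = 0, upper = 1) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  Z <- pnorm(b) - pnorm(a)
  m <- mean + sd * (dnorm(a) - dnorm(b)) / Z
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                 ((dnorm(a) - dnorm(b)) / Z)^2)
  list(mean = m, sd = sqrt(v))
}

# parameter grid used by the oracle-equivalence checks
oracle_grid <- function() {
  tidyr::expand_grid(bvf = c(0.005, 0.01, 0.05, 0.1, 0.3, 0.5),
                     rb_over_L = c(0.01, 0.068, 0.2, 1.0))
}
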