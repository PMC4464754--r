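test_that("model_params validates its invariants", {
  p <- model_params(0.038, 5, 40, 0.25)
  expect_equal(p$rb_over_L, 5 / 40)
  expect_error(model_params(0, 5, 40, 0.25), class = "vasckill_domain_error")
  expect_error(model_params(1, 5, 40, 0.25), class = "vasckill_domain_error")
  expect_error(model_params(0.04, -1, 40, 0.25),
               class = "vasckill_domain_error")
  expect_error(model_params(0.04, 5, 40, 1.2),
               class = "vasckill_domain_error")
  # D and lambda must be consistent with L = sqrt(D / lambda)
  expect_silent(model_params(0.04, 5, 40, 0.25,
                             D_um2_s = 160, lambda_per_s = 0.1))
  expect_error(model_params(0.04, 5, 41, 0.25,
                            D_um2_s = 160, lambda_per_s = 0.1),
               class = "vasckill_validation_error")
})

test_that("tissue geometry follows BVF = (rb/rt)^2", {
  g <- tissue_geometry(0.04, 0.068)
  expect_equal(g$rt_scaled, 0.068 / sqrt(0.04))
  expect_gt(g$rt_scaled, g$rb_scaled)
})

test_that("concentration equals 1 at the vessel wall and decays", {
  expect_equal(scaled_concentration(0.068, 0.068), 1, tolerance = 1e-12)
  r <- seq(0.068, 5, length.out = 200)
  sig <- scaled_concentration(r, 0.068)
  expect_true(all(sig > 0 & sig <= 1))
  expect_true(all(diff(sig) < 0))
  expect_error(scaled_concentration(0.05, 0.068),
               class = "vasckill_domain_error")
  expect_error(scaled_concentration(0.3, -1),
               class = "vasckill_domain_error")
})

test_that("concentration matches an independent finite-difference BVP solve", {
  solver <- fd_concentration_solver(0.068)
  for (r in c(0.1, 0.3, 1, 3)) {
    expect_equal(scaled_concentration(r, 0.068), solver(r),
                 tolerance = 1e-6)
  }
})

test_that("concentration_profile returns a valid decreasing profile", {
  prof <- concentration_profile(0.068, r_max = 3, n = 100)
  expect_equal(prof$concentration[1], 1, tolerance = 1e-12)
  expect_true(all(diff(prof$scaled_radius) > 0))
  expect_true(all(prof$scaled_radius >= 0.068))
  expect_true(all(diff(prof$concentration) < 0))
})

test_that("kill fraction agrees with the quadrature oracle on the grid", {
  grid <- oracle_grid()
  for (i in seq_len(nrow(grid))) {
    p <- model_params(grid$bvf[i], grid$rb_over_L[i] * 40, 40, 0.25)
    cf <- kill_fraction(p)
    or <- kill_fraction_oracle(p)
    expect_lt(abs(cf - or) / or, 1e-6)
  }
})

test_that("kill fraction honours its analytic limits and bounds", {
  # zero in-vitro kill is a hard multiplicative zero
  expect_equal(kill_fraction(model_params(0.3, 5, 40, 0)), 0)
  expect_equal(kill_fraction_oracle(model_params(0.3, 5, 40, 0)), 0)
  # vanishing annulus: BVF -> 1 recovers the in-vitro fraction
  expect_equal(kill_fraction(model_params(1 - 1e-9, 2.72, 40, 0.25)), 0.25,
               tolerance = 1e-6)
  expect_equal(kill_fraction_oracle(model_params(1 - 1e-9, 2.72, 40, 0.25)),
               0.25, tolerance = 1e-6)
  # r_b/L -> 0 at fixed BVF approaches the in-vitro fraction; the
  # approach is logarithmic in rb/L, so assert monotone approach and
  # closeness at an extreme argument
  seq_fk <- sapply(c(1e-2, 1e-6, 1e-12, 1e-28),
                   function(rb) kill_fraction(model_params(0.04, rb, 40,
                                                           0.25)))
  expect_true(all(diff(seq_fk) > 0))
  expect_equal(seq_fk[4], 0.25, tolerance = 0.03)
  # r_b/L -> infinity kills nothing beyond the wall
  expect_lt(kill_fraction(model_params(0.04, 4000, 40, 0.25)), 1e-3)
  # bounds on a random parameter sweep
  set.seed(42)
  for (i in 1:50) {
    p <- model_params(runif(1, 0.003, 0.9), runif(1, 0.5, 20),
                      runif(1, 10, 100), runif(1))
    fk <- kill_fraction(p)
    expect_gte(fk, 0)
    expect_lte(fk, p$fkill_m + 1e-12)
  }
})

test_that("small scaled radii match high-precision reference values", {
  # frozen from a 120-digit evaluation of the annulus-averaged K0 profile;
  # naive double-precision evaluation of the closed form loses all digits
  # below rb/L ~ 1e-8
  refs <- tibble::tribble(
    ~bvf, ~rb_over_L, ~factor,
    0.04, 5e-2,    0.62858926816004748,
    0.04, 1e-2,    0.75107751098863942,
    0.3,  1e-2,    0.92378365943580274,
    0.04, 2.5e-9,  0.94094748081447165,
    0.3,  1e-12,   0.98702630233675730,
    0.04, 2.5e-30, 0.98276880223285870)
  for (i in seq_len(nrow(refs))) {
    p <- model_params(refs$bvf[i], refs$rb_over_L[i] * 40, 40, 1)
    expect_equal(kill_fraction(p), refs$factor[i], tolerance = 1e-9)
  }
})

test_that("kill fraction is monotone in each parameter", {
  fk <- function(bvf, rb, L) kill_fraction(model_params(bvf, rb, L, 0.25))
  bvfs <- seq(0.005, 0.95, length.out = 40)
  expect_true(all(diff(sapply(bvfs, fk, rb = 5, L = 40)) > 0))
  rbs <- seq(0.5, 50, length.out = 40)
  expect_true(all(diff(sapply(rbs, function(r) fk(0.04, r, 40))) < 0))
  Ls <- seq(10, 200, length.out = 40)
  expect_true(all(diff(sapply(Ls, function(L) fk(0.04, 5, L))) > 0))
})

test_that("kill fraction is exactly linear in the in-vitro fraction", {
  base <- kill_fraction(model_params(0.04, 5, 40, 1))
  for (fm in c(0.1, 0.25, 0.5, 0.77)) {
    expect_identical(kill_fraction(model_params(0.04, 5, 40, fm)),
                     fm * base)
  }
})

test_that("kill fraction survives extreme scaled radii without overflow", {
  # large rb/L underflows unscaled Bessel functions; scaled forms must not
  fk <- kill_fraction(model_params(0.04, 800, 10, 0.25))
  expect_true(is.finite(fk))
  expect_gte(fk, 0)
})

test_that("predict_curve is element-wise consistent and increasing", {
  grid <- seq(0.01, 0.5, length.out = 25)
  curve <- predict_curve(0.25, 0.068, grid)
  expect_true(all(diff(curve$f_kill) > 0))
  expect_true(all(curve$f_kill <= 0.25))
  for (i in c(1, 10, 25)) {
    p <- model_params(grid[i], 0.068 * 40, 40, 0.25)
    expect_equal(curve$f_kill[i], kill_fraction_oracle(p),
                 tolerance = 1e-6)
  }
  expect_equal(predict_curve(0, 0.068, grid)$f_kill, rep(0, 25))
  expect_error(predict_curve(0.25, 0.068, c(0.5, 0.1)),
               class = "vasckill_domain_error")
  expect_error(predict_curve(0.25, 0.068, c(0.1, 1.2)),
               class = "vasckill_domain_error")
})
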