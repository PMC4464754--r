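test_that("synthetic_config validates its fields", {
  expect_s3_class(synthetic_config(), "synthetic_config")
  expect_error(synthetic_config(bvf_support = c(0.2, 0.1)),
               class = "vasckill_validation_error")
  expect_error(synthetic_config(kill_noise_sd = -1),
               class = "vasckill_domain_error")
  expect_error(synthetic_config(n_sections = c(sensitive = 5)),
               class = "vasckill_validation_error")
})

test_that("all generators are deterministic under a fixed seed", {
  cfg <- synthetic_config(seed = 314)
  expect_identical(generate_sections(cfg), generate_sections(cfg))
  expect_identical(generate_kill_dataset(cfg), generate_kill_dataset(cfg))
  expect_identical(generate_dose_response(cfg),
                   generate_dose_response(cfg))
  # a different seed produces different draws
  expect_false(identical(
    generate_kill_dataset(cfg)$data$bvf,
    generate_kill_dataset(synthetic_config(seed = 315))$data$bvf))
})

test_that("sections follow the study design and configured moments", {
  cfg <- synthetic_config(seed = 2)
  sim <- generate_sections(cfg)
  counts <- sim$sections |>
    dplyr::distinct(line, section_index) |>
    dplyr::count(line)
  expect_equal(counts$n[counts$line == "sensitive"], 5L)
  expect_equal(counts$n[counts$line == "resistant"], 6L)
  expect_equal(dplyr::n_distinct(sim$sections$roi_index), 3L)
  expect_true(all(sim$sections$stained_area <= sim$sections$total_area))
  # zero marker noise collapses every ROI onto its group mean
  sim0 <- generate_sections(synthetic_config(seed = 2,
                                             marker_sd_scale = 0))
  s0 <- summarize_markers(sim0$sections)
  joined <- dplyr::inner_join(s0, marker_reference(),
                              by = c("marker", "line", "treated"))
  expect_equal(joined$mean_fraction.x, joined$mean_fraction.y,
               tolerance = 1e-6)
  expect_equal(joined$sd_fraction.x, rep(0, nrow(joined)),
               tolerance = 1e-6)
})

test_that("large-sample necrosis mean matches the configured target", {
  cfg <- synthetic_config(seed = 6, rois_per_section = 200L)
  sim <- generate_sections(cfg)
  necro <- suppressWarnings(summarize_markers(sim$sections)) |>
    dplyr::filter(marker == "necrosis", line == "sensitive", treated)
  se <- 0.05 / sqrt(necro$n)
  expect_lt(abs(necro$mean_fraction - 0.121), 3 * se)
})

test_that("vessels mix capillaries and veins as configured", {
  cfg <- synthetic_config(seed = 3, vessels_per_section = 200L)
  sim <- generate_sections(cfg)
  share <- mean(sim$vessels$vessel_class == "capillary")
  expect_lt(abs(share - 0.9), 0.03)
  expect_true(all(sim$vessels$extent1_um > 0))
  r <- estimate_vessel_radius(sim$vessels)
  expect_lt(abs(r$mean_um - 5.5), 0.5) # 0.9*5 + 0.1*10 um mixture mean
})

test_that("kill data round-trips through rescaling at zero noise", {
  cfg <- synthetic_config(seed = 4, kill_noise_sd = 0)
  sim <- generate_kill_dataset(cfg)
  expect_equal(nrow(sim$data), 11L)
  # ratio 1: dead fractions equal the closed-form model values
  cfg1 <- synthetic_config(seed = 4, kill_noise_sd = 0, kill_ratio = 1)
  sim1 <- generate_kill_dataset(cfg1)
  expect_equal(sim1$data$dead_fraction, sim1$truth$true_kill)
  # ratio 3.5: rescaling restores the model values exactly
  restored <- rescale_resistant(sim$data, cfg$kill_ratio)
  expect_equal(restored$dead_fraction, sim$truth$true_kill,
               tolerance = 1e-12)
  expect_false(attr(sim$data, "rescaled"))
})

test_that("generated kill data validates against the calibration reader", {
  sim <- generate_kill_dataset(synthetic_config(seed = 12))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(sim$data, path)
  report <- validate_inputs(list(killdata = path))
  expect_equal(nrow(report), 0L)
})

test_that("dose-response generator round-trips through the 4PL fitter", {
  cfg <- synthetic_config(dose_noise_sd = 0)
  curves <- generate_dose_response(cfg)
  expect_equal(nrow(curves), 18L)
  expect_true(all(curves$concentration_nM > 0))
  fits <- curves |>
    dplyr::group_split(line) |>
    purrr::map(fit_hill_ic50)
  ic50 <- purrr::map_dbl(fits, "ic50_nM")
  names(ic50) <- purrr::map_chr(curves |>
                                  dplyr::group_split(line) |>
                                  purrr::map(~ .x$line[1]), identity)
  expect_equal(unname(ic50["sensitive"]), 3.5, tolerance = 1e-6)
  expect_equal(unname(ic50["resistant"]), 46.2, tolerance = 1e-6)
  fd <- fold_difference(ic50["resistant"], ic50["sensitive"])
  expect_equal(fd$fold, 13.2, tolerance = 0.01)
  expect_equal(fd$fold_nearest, 13L)
})
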