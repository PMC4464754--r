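test_that("stain_fraction computes and validates the stained share", {
  expect_equal(stain_fraction(0, 1000), 0)
  expect_equal(stain_fraction(500, 1000), 0.5)
  expect_equal(stain_fraction(121, 1000), 0.121)
  expect_error(stain_fraction(10, 0), class = "vasckill_validation_error")
  expect_error(stain_fraction(1100, 1000),
               class = "vasckill_validation_error")
})

test_that("stain_fraction is invariant to a common area scale", {
  set.seed(11)
  stained <- runif(20, 0, 500)
  total <- stained + runif(20, 1, 500)
  for (k in c(0.5, 3, 1e4)) {
    expect_equal(stain_fraction(k * stained, k * total),
                 stain_fraction(stained, total))
  }
})

test_that("summarize_markers groups by marker, line and treatment", {
  rows <- tibble::tibble(
    line = "sensitive", treated = TRUE, section_index = 1L,
    roi_index = 1:2, marker = "necrosis",
    stained_area = c(100, 300), total_area = 1000)
  s <- summarize_markers(rows)
  expect_equal(nrow(s), 1L)
  expect_equal(s$mean_fraction, 0.2)
  expect_equal(s$sd_fraction, sd(c(0.1, 0.3)))
  expect_equal(s$n, 2L)
  # single measurement: sd reported as 0
  s1 <- summarize_markers(rows[1, ])
  expect_equal(s1$sd_fraction, 0)
  expect_equal(s1$n, 1L)
  expect_error(summarize_markers(rows[0, ]),
               class = "vasckill_validation_error")
})

test_that("summarize_markers warns when a line has too many sections", {
  rows <- tidyr::expand_grid(
    line = "sensitive", treated = TRUE, section_index = 1:7,
    roi_index = 1L, marker = "necrosis") |>
    dplyr::mutate(stained_area = 100, total_area = 1000)
  expect_warning(summarize_markers(rows), "sections")
})

test_that("summarize_markers recovers the generator's configured means", {
  cfg <- synthetic_config(seed = 101, rois_per_section = 100L)
  sim <- generate_sections(cfg)
  s <- summarize_markers(sim$sections) |>
    dplyr::inner_join(marker_reference(),
                      by = c("marker", "line", "treated"),
                      suffix = c("", "_true"))
  # sampling is a [0, 1]-truncated normal, so compare against the
  # truncated distribution's analytic mean, within 3 standard errors
  for (i in seq_len(nrow(s))) {
    if (s$sd_fraction_true[i] == 0) {
      expect_equal(s$mean_fraction[i], s$mean_fraction_true[i],
                   tolerance = 1e-6)
    } else {
      mom <- truncnorm_moments(s$mean_fraction_true[i],
                               s$sd_fraction_true[i])
      slack <- 3 * mom$sd / sqrt(s$n[i])
      expect_lt(abs(s$mean_fraction[i] - mom$mean), slack)
    }
  }
})

test_that("marker_ratio reproduces the reported fold changes", {
  ref <- marker_reference()
  pick <- function(m, l, tr) {
    dplyr::filter(ref, .data$marker == m, .data$line == l,
                  .data$treated == tr)
  }
  necro <- marker_ratio(pick("necrosis", "sensitive", TRUE),
                        pick("necrosis", "sensitive", FALSE))
  expect_equal(round(necro), 24)
  expect_equal(necro, 0.121 / 0.005)
  apop <- marker_ratio(pick("apoptosis", "resistant", FALSE),
                       pick("apoptosis", "resistant", TRUE))
  expect_equal(round(apop), 4)
  # reciprocal pairs multiply to one; equal means give one
  expect_equal(necro * marker_ratio(pick("necrosis", "sensitive", FALSE),
                                    pick("necrosis", "sensitive", TRUE)), 1)
  a <- tibble::tibble(marker = "cd31", mean_fraction = 0.03)
  expect_equal(marker_ratio(a, a), 1)
  b <- tibble::tibble(marker = "hif1a", mean_fraction = 0.03)
  expect_error(marker_ratio(a, b), class = "vasckill_validation_error")
  z <- tibble::tibble(marker = "cd31", mean_fraction = 0)
  expect_error(marker_ratio(a, z), class = "vasckill_validation_error")
})

test_that("estimate_bvf maps CD31 fraction with optional correction", {
  expect_equal(estimate_bvf(0.031), 0.031)
  expect_equal(estimate_bvf(0, 2), 0)
  expect_equal(estimate_bvf(0.045, 1.5), 0.0675)
  expect_warning(out <- estimate_bvf(0.9, 1.5), "clamped")
  expect_equal(out, 1)
})

test_that("vessel radius averages two orthogonal extents halved", {
  one <- function(e1, e2) {
    estimate_vessel_radius(tibble::tibble(extent1_um = e1,
                                          extent2_um = e2))
  }
  expect_equal(one(10, 10)$mean_um, 5)   # capillary-sized
  expect_equal(one(20, 20)$mean_um, 10)  # vein-sized
  expect_equal(one(8, 12)$mean_um, 5)
  expect_equal(one(10, 10)$sd_um, 0)
  two <- estimate_vessel_radius(
    tibble::tibble(extent1_um = c(10, 20), extent2_um = c(10, 20)))
  expect_equal(two$mean_um, 7.5)
  expect_equal(two$sd_um, sd(c(5, 10)))
  expect_error(one(-1, 10), class = "vasckill_validation_error")
  expect_error(estimate_vessel_radius(
    tibble::tibble(extent1_um = numeric(), extent2_um = numeric())),
    class = "vasckill_validation_error")
})

test_that("penetration distance halves the hypoxia onset distance", {
  expect_equal(estimate_penetration_distance(rep(80, 4))$mean_um, 40)
  expect_equal(estimate_penetration_distance(c(60, 100))$mean_um, 40)
  expect_equal(estimate_penetration_distance(c(60, 100))$sd_um,
               0.5 * sd(c(60, 100)))
  expect_equal(estimate_penetration_distance(c(60, 100), 1)$mean_um, 80)
  expect_error(estimate_penetration_distance(numeric()),
               class = "vasckill_validation_error")
  expect_error(estimate_penetration_distance(c(10, -5)),
               class = "vasckill_validation_error")
})
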