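# Synthetic-data generators: every input the pipeline consumes, with the
# statistical structure the analysis assumes, so all stages can be exercised
# end to end without external data.

#' Synthetic study configuration
#'
#' Collects every knob of the synthetic generators with defaults matching
#' the study conditions: 5 sensitive + 6 resistant sections with 3 ROIs
#' each, marker group means/SDs from [marker_reference()], kill data
#' generated from the closed-form model at \eqn{f^{M}_{kill} = 0.25} and
#' \eqn{r_b/L = 0.068} with additive Gaussian measurement noise (SD 0.02),
#' a 3.5 in-vitro sensitive/resistant kill ratio, BVF sampled from a
#' truncated normal (mean 0.038, SD 0.015, support (0.003, 0.2)), and a
#' 9-point 3x dilution dose-response design from 10 \eqn{\mu M} with IC50s
#' of 3.5 nM (sensitive) and 46.2 nM (resistant).
#'
#' @param seed Integer seed; all generators are deterministic given it.
#' @param n_sections Named integer vector, sections per line.
#' @param rois_per_section ROIs measured per section.
#' @param markers Marker mean/SD table as from [marker_reference()].
#' @param marker_sd_scale Multiplier on the marker SDs (0 gives noiseless
#'   sections).
#' @param total_area Total pixel count per ROI.
#' @param vessels_per_section,capillary_fraction Vessel sampling design:
#'   count per section and the capillary share (the remainder are veins).
#' @param capillary_diameter_um,vein_diameter_um,vessel_diameter_sd_um
#'   Mean diameters of the two vessel classes and the SD of the sampled
#'   cross-section extents.
#' @param fkill_m,rb_over_L True model parameters behind the kill data.
#' @param kill_ratio True in-vitro sensitive/resistant kill ratio.
#' @param kill_noise_sd Additive Gaussian SD on dead fractions.
#' @param bvf_mean,bvf_sd,bvf_support Truncated-normal BVF sampling
#'   distribution.
#' @param ic50_sensitive_nM,ic50_resistant_nM,hill_slope,dose_top,dose_bottom
#'   Dose-response generator: per-line IC50s and the shared 4PL shape.
#' @param dose_top_nM,dose_dilution,n_doses Dilution design: top
#'   concentration, serial dilution factor, number of points.
#' @param dose_noise_sd Additive Gaussian SD on viability fractions.
#' @return A validated list of class `synthetic_config`.
#' @examples
#' cfg <- synthetic_config(seed = 7)
#' sim <- generate_kill_dataset(cfg)
#' head(sim$data)
#' @export
synthetic_config <- function(seed = 1L,
                             n_sections = c(sensitive = 5L, resistant = 6L),
                             rois_per_section = 3L,
                             markers = marker_reference(),
                             marker_sd_scale = 1,
                             total_area = 1e6,
                             vessels_per_section = 10L,
                             capillary_fraction = 0.9,
                             capillary_diameter_um = 10,
                             vein_diameter_um = 20,
                             vessel_diameter_sd_um = 4,
                             fkill_m = 0.25,
                             rb_over_L = 0.068,
                             kill_ratio = 3.5,
                             kill_noise_sd = 0.02,
                             bvf_mean = 0.038,
                             bvf_sd = 0.015,
                             bvf_support = c(0.003, 0.2),
                             ic50_sensitive_nM = 3.5,
                             ic50_resistant_nM = 46.2,
                             hill_slope = 1,
                             dose_top = 1,
                             dose_bottom = 0,
                             dose_top_nM = 10000,
                             dose_dilution = 3,
                             n_doses = 9L,
                             dose_noise_sd = 0) {
  check_number(seed, "seed")
  if (!all(c("sensitive", "resistant") %in% names(n_sections)) ||
      any(n_sections < 1L)) {
    abort("`n_sections` must name counts >= 1 for sensitive and resistant.",
          class = "vasckill_validation_error")
  }
  check_number(rois_per_section, "rois_per_section", 1, Inf)
  check_columns(markers, c("marker", "line", "treated", "mean_fraction",
                           "sd_fraction"), "markers")
  if (any(markers$sd_fraction < 0) || any(markers$mean_fraction < 0) ||
      any(markers$mean_fraction > 1)) {
    abort("Marker means must be fractions and SDs non-negative.",
          class = "vasckill_validation_error")
  }
  check_number(marker_sd_scale, "marker_sd_scale", 0, Inf)
  check_number(kill_noise_sd, "kill_noise_sd", 0, Inf)
  check_number(dose_noise_sd, "dose_noise_sd", 0, Inf)
  check_number(fkill_m, "fkill_m", 0, 1)
  check_number(rb_over_L, "rb_over_L", 0, Inf, allow_boundary = FALSE)
  check_number(kill_ratio, "kill_ratio", 0, Inf, allow_boundary = FALSE)
  check_number(bvf_mean, "bvf_mean", 0, 1, allow_boundary = FALSE)
  check_number(bvf_sd, "bvf_sd", 0, Inf)
  if (length(bvf_support) != 2L || bvf_support[1] <= 0 ||
      bvf_support[2] >= 1 || bvf_support[1] >= bvf_support[2]) {
    abort("`bvf_support` must be an increasing pair inside (0, 1).",
          class = "vasckill_validation_error")
  }
  check_number(capillary_fraction, "capillary_fraction", 0, 1)
  structure(
    list(seed = as.integer(seed), n_sections = n_sections,
         rois_per_section = as.integer(rois_per_section),
         markers = as_tibble(markers), marker_sd_scale = marker_sd_scale,
         total_area = total_area,
         vessels_per_section = as.integer(vessels_per_section),
         capillary_fraction = capillary_fraction,
         capillary_diameter_um = capillary_diameter_um,
         vein_diameter_um = vein_diameter_um,
         vessel_diameter_sd_um = vessel_diameter_sd_um,
         fkill_m = fkill_m, rb_over_L = rb_over_L, kill_ratio = kill_ratio,
         kill_noise_sd = kill_noise_sd, bvf_mean = bvf_mean,
         bvf_sd = bvf_sd, bvf_support = bvf_support,
         ic50_sensitive_nM = ic50_sensitive_nM,
         ic50_resistant_nM = ic50_resistant_nM, hill_slope = hill_slope,
         dose_top = dose_top, dose_bottom = dose_bottom,
         dose_top_nM = dose_top_nM, dose_dilution = dose_dilution,
         n_doses = as.integer(n_doses), dose_noise_sd = dose_noise_sd),
    class = "synthetic_config")
}

check_config <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    abort("`config` must be a synthetic_config object.",
          class = "vasckill_validation_error")
  }
  invisible(config)
}

#' Generate synthetic histology section and vessel tables
#'
#' Draws per-ROI stained/total areas whose group means and SDs follow the
#' configured marker table (truncated-normal stain fractions), and vessel
#' cross-sections from a capillary/vein mixture (default 90% capillaries
#' of ~10 \eqn{\mu m} diameter, 10% veins of ~20 \eqn{\mu m}).
#'
#' @param config A [synthetic_config()].
#' @return A list with `sections` (the `sections.csv` schema), `vessels`
#'   (the `vessels.csv` schema) and `truth` (the generating parameters).
#' @examples
#' sim <- generate_sections(synthetic_config(seed = 1))
#' dplyr::count(sim$sections, line, treated)
#' @export
generate_sections <- function(config = synthetic_config()) {
  check_config(config)
  with_preserved_seed(config$seed, {
    design <- tidyr::expand_grid(
      config$markers,
      roi_index = seq_len(config$rois_per_section)
    ) |>
      dplyr::left_join(
        tibble(line = names(config$n_sections),
               n_sec = as.integer(config$n_sections)),
        by = "line") |>
      tidyr::uncount(.data$n_sec, .id = "section_index")
    frac <- rtruncnorm(nrow(design),
                       mean = design$mean_fraction,
                       sd = design$sd_fraction * config$marker_sd_scale,
                       lower = 0, upper = 1)
    sections <- design |>
      dplyr::transmute(
        line = .data$line, treated = .data$treated,
        section_index = as.integer(.data$section_index),
        roi_index = as.integer(.data$roi_index),
        marker = .data$marker,
        stained_area = round(frac * config$total_area),
        total_area = config$total_area
      ) |>
      dplyr::arrange(.data$line, .data$treated, .data$section_index,
                     .data$roi_index, .data$marker)
    n_vessels <- sum(config$n_sections) * config$vessels_per_section
    vessel_design <- tibble(line = names(config$n_sections),
                            n_sec = as.integer(config$n_sections)) |>
      tidyr::uncount(.data$n_sec, .id = "section_index") |>
      tidyr::expand_grid(vessel_id = seq_len(config$vessels_per_section))
    is_cap <- runif(n_vessels) < config$capillary_fraction
    diam <- ifelse(is_cap, config$capillary_diameter_um,
                   config$vein_diameter_um)
    vessels <- vessel_design |>
      dplyr::transmute(
        line = .data$line,
        section_index = as.integer(.data$section_index),
        vessel_id = as.integer(.data$vessel_id),
        extent1_um = rtruncnorm(n_vessels, diam,
                                config$vessel_diameter_sd_um, 0.5, Inf),
        extent2_um = rtruncnorm(n_vessels, diam,
                                config$vessel_diameter_sd_um, 0.5, Inf),
        vessel_class = ifelse(is_cap, "capillary", "vein")
      )
    list(sections = sections, vessels = vessels,
         truth = list(markers = config$markers,
                      capillary_fraction = config$capillary_fraction,
                      capillary_diameter_um = config$capillary_diameter_um,
                      vein_diameter_um = config$vein_diameter_um))
  })
}

#' Generate a synthetic per-section kill dataset
#'
#' Samples one BVF per section from the configured truncated normal, sets
#' the sensitive line's dead fraction to the closed-form kill fraction at
#' the true parameters plus noise, and the resistant line's to the same
#' divided by the in-vitro kill ratio plus noise (so that
#' [rescale_resistant()] restores a common scale). Values are clipped to
#' \[0, 1\] with a message.
#'
#' @param config A [synthetic_config()].
#' @return A list with `data` (columns `line`, `section_index`, `bvf`,
#'   `dead_fraction`; attribute `rescaled = FALSE`) and `truth` (true
#'   parameters and the noiseless kill values per point).
#' @examples
#' sim <- generate_kill_dataset(synthetic_config(seed = 2))
#' sim$data
#' @export
generate_kill_dataset <- function(config = synthetic_config()) {
  check_config(config)
  with_preserved_seed(config$seed, {
    pts <- tibble(line = names(config$n_sections),
                  n_sec = as.integer(config$n_sections)) |>
      tidyr::uncount(.data$n_sec, .id = "section_index")
    n <- nrow(pts)
    bvf <- rtruncnorm(n, config$bvf_mean, config$bvf_sd,
                      config$bvf_support[1], config$bvf_support[2])
    true_kill <- config$fkill_m * kill_factor(bvf, config$rb_over_L)
    scale <- ifelse(pts$line == "resistant", 1 / config$kill_ratio, 1)
    dead <- true_kill * scale + rnorm(n, 0, config$kill_noise_sd)
    n_clip <- sum(dead < 0 | dead > 1)
    if (n_clip > 0L) {
      inform(sprintf("%d dead fraction(s) clipped to [0, 1].", n_clip))
    }
    dead <- pmin(pmax(dead, 0), 1)
    data <- pts |>
      dplyr::transmute(line = .data$line,
                       section_index = as.integer(.data$section_index),
                       bvf = bvf, dead_fraction = dead)
    attr(data, "rescaled") <- FALSE
    list(data = data,
         truth = list(fkill_m = config$fkill_m,
                      rb_over_L = config$rb_over_L,
                      kill_ratio = config$kill_ratio,
                      kill_noise_sd = config$kill_noise_sd,
                      bvf = bvf, true_kill = true_kill))
  })
}

#' Generate synthetic dose-response curves for both lines
#'
#' A serial-dilution design (default 9 points, 3x dilution from 10
#' \eqn{\mu M}) with 4PL viability at each line's configured IC50 and
#' optional additive noise, clipped to \[0, 1\].
#'
#' @param config A [synthetic_config()].
#' @return A tibble with columns `line`, `concentration_nM` (ascending),
#'   `viability_fraction`, `replicate`.
#' @examples
#' generate_dose_response(synthetic_config(dose_noise_sd = 0))
#' @export
generate_dose_response <- function(config = synthetic_config()) {
  check_config(config)
  with_preserved_seed(config$seed, {
    conc <- config$dose_top_nM /
      config$dose_dilution^((config$n_doses - 1):0)
    ic50 <- c(sensitive = config$ic50_sensitive_nM,
              resistant = config$ic50_resistant_nM)
    purrr::map_dfr(names(ic50), function(ln) {
      v <- hill_4pl(conc, config$dose_top, config$dose_bottom,
                    ic50[[ln]], config$hill_slope)
      if (config$dose_noise_sd > 0) {
        v <- pmin(pmax(v + rnorm(length(v), 0, config$dose_noise_sd), 0), 1)
      }
      tibble(line = ln, concentration_nM = conc, viability_fraction = v,
             replicate = 1L)
    })
  })
}
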