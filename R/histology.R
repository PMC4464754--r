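# Histology module: turn tabulated IHC stain measurements into model
# parameters (BVF, r_b, L) and per-marker summary tables and fold changes.

#' Stained-area fraction of an ROI measurement
#'
#' The fraction of tissue positive for a marker within a region of interest:
#' stained area over total (stained + unstained) area. Vectorized.
#'
#' @param stained_area Stained pixel count(s), >= 0.
#' @param total_area Total pixel count(s), > 0.
#' @return Fraction(s) in \[0, 1\].
#' @examples
#' stain_fraction(121, 1000)
#' @export
stain_fraction <- function(stained_area, total_area) {
  if (any(!is.finite(total_area)) || any(total_area <= 0)) {
    abort("`total_area` must be positive.",
          class = "vasckill_validation_error")
  }
  if (any(!is.finite(stained_area)) || any(stained_area < 0)) {
    abort("`stained_area` must be non-negative.",
          class = "vasckill_validation_error")
  }
  if (any(stained_area > total_area)) {
    abort("`stained_area` exceeds `total_area`.",
          class = "vasckill_validation_error")
  }
  stained_area / total_area
}

#' Summarize per-ROI stain measurements by marker and group
#'
#' Collapses a table of per-ROI stained/total areas into one row per
#' (marker, line, treated) group with the mean, sample SD and count of the
#' per-ROI stain fractions — the same shape as the study-style IHC summary
#' table the calibration consumes.
#'
#' @param rows A data frame with columns `line`, `treated`, `section_index`,
#'   `roi_index`, `marker`, `stained_area`, `total_area` (the `sections.csv`
#'   schema; see [read_sections()]).
#' @return A tibble with columns `marker`, `line`, `treated`,
#'   `mean_fraction`, `sd_fraction`, `n`. Single-measurement groups report
#'   `sd_fraction = 0`.
#' @examples
#' rows <- tibble::tibble(
#'   line = "sensitive", treated = TRUE, section_index = 1,
#'   roi_index = 1:2, marker = "necrosis",
#'   stained_area = c(100, 300), total_area = 1000
#' )
#' summarize_markers(rows)
#' @export
summarize_markers <- function(rows) {
  check_columns(rows, c("line", "treated", "marker",
                        "stained_area", "total_area"), "rows")
  if (nrow(rows) == 0L) {
    abort("`rows` is empty.", class = "vasckill_validation_error")
  }
  n_sections <- rows |>
    dplyr::distinct(.data$line, .data$section_index) |>
    dplyr::count(.data$line)
  cap <- c(sensitive = 5L, resistant = 6L)
  over <- n_sections |>
    dplyr::filter(.data$line %in% names(cap),
                  .data$n > cap[as.character(.data$line)])
  if (nrow(over) > 0L) {
    warn(sprintf(
      "More sections than the study design (5 sensitive / 6 resistant): %s.",
      paste(over$line, over$n, sep = "=", collapse = ", ")))
  }
  rows |>
    dplyr::mutate(fraction = stain_fraction(.data$stained_area,
                                            .data$total_area)) |>
    dplyr::group_by(.data$marker, .data$line, .data$treated) |>
    dplyr::summarise(
      mean_fraction = mean(.data$fraction),
      sd_fraction = if (dplyr::n() > 1L) sd(.data$fraction) else 0,
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Fold change between two marker summaries
#'
#' Ratio of mean stain fractions between two groups of the same marker,
#' e.g. treated over untreated necrosis.
#'
#' @param a,b One-row data frames (or single rows of the
#'   [summarize_markers()] output) with columns `marker` and
#'   `mean_fraction`; the ratio is `a` over `b`.
#' @return A single number, `a$mean_fraction / b$mean_fraction`.
#' @examples
#' a <- tibble::tibble(marker = "necrosis", mean_fraction = 0.121)
#' b <- tibble::tibble(marker = "necrosis", mean_fraction = 0.005)
#' marker_ratio(a, b) # ~ 24x
#' @export
marker_ratio <- function(a, b) {
  for (x in list(a, b)) {
    check_columns(x, c("marker", "mean_fraction"), "marker summary")
    if (nrow(x) != 1L) {
      abort("`a` and `b` must be single marker-summary rows.",
            class = "vasckill_validation_error")
    }
  }
  if (!identical(as.character(a$marker), as.character(b$marker))) {
    abort(sprintf("Markers differ: '%s' vs '%s'.", a$marker, b$marker),
          class = "vasckill_validation_error")
  }
  if (b$mean_fraction <= 0) {
    abort(paste("Denominator mean fraction is zero; use a floor or exclude",
                "the group."), class = "vasckill_validation_error")
  }
  a$mean_fraction / b$mean_fraction
}

#' Blood volume fraction from CD31 staining
#'
#' Estimates the blood volume fraction from the CD31 (endothelium)
#' stained-area fraction, assuming BVF proportional to vascular density.
#' The default correction factor of 1 maps the stain fraction directly to
#' BVF; a different factor can express, e.g., a lumen-vs-endothelium
#' correction.
#'
#' @param cd31_fraction CD31 stain fraction in \[0, 1\].
#' @param correction Positive multiplicative factor (default 1).
#' @return Estimated BVF; values that would exceed 1 are clamped with a
#'   warning.
#' @examples
#' estimate_bvf(0.031)
#' @export
estimate_bvf <- function(cd31_fraction, correction = 1) {
  check_number(cd31_fraction, "cd31_fraction", 0, 1)
  check_number(correction, "correction", 0, Inf, allow_boundary = FALSE)
  out <- cd31_fraction * correction
  if (out > 1) {
    warn(sprintf("Estimated BVF %g exceeds 1; clamped.", out))
    out <- 1
  }
  out
}

#' Mean vessel radius from cross-section extents
#'
#' Each vessel contributes the mean of two orthogonal cross-section extents
#' (diameters); the radius is half that, i.e. `(extent1 + extent2) / 4`.
#' Returns the mean and sample SD over vessels.
#'
#' @param vessels Data frame with columns `extent1_um` and `extent2_um`
#'   (the `vessels.csv` schema; see [read_vessels()]).
#' @return A one-row tibble with `mean_um`, `sd_um` (0 for a single
#'   vessel) and `n`.
#' @examples
#' estimate_vessel_radius(tibble::tibble(extent1_um = 10, extent2_um = 10))
#' @export
estimate_vessel_radius <- function(vessels) {
  check_columns(vessels, c("extent1_um", "extent2_um"), "vessels")
  if (nrow(vessels) == 0L) {
    abort("`vessels` is empty.", class = "vasckill_validation_error")
  }
  ext <- c(vessels$extent1_um, vessels$extent2_um)
  if (any(!is.finite(ext)) || any(ext <= 0)) {
    abort("Vessel extents must be positive.",
          class = "vasckill_validation_error")
  }
  r <- (vessels$extent1_um + vessels$extent2_um) / 4
  tibble(
    mean_um = mean(r),
    sd_um = if (length(r) > 1L) sd(r) else 0,
    n = length(r)
  )
}

#' Drug penetration distance from hypoxia onset distances
#'
#' The drug diffusion penetration distance \eqn{L} is taken as a fixed
#' fraction (default half, the best-case bound relative to oxygen) of the
#' measured distance from vessel cross-sections to the onset of hypoxia
#' staining.
#'
#' @param hypoxia_distances_um Positive distances, \eqn{\mu m}.
#' @param o2_halving Scale factor applied to the mean and SD (default 0.5).
#' @return A one-row tibble with `mean_um`, `sd_um` and `n`.
#' @examples
#' estimate_penetration_distance(c(60, 100))
#' @export
estimate_penetration_distance <- function(hypoxia_distances_um,
                                          o2_halving = 0.5) {
  if (length(hypoxia_distances_um) == 0L) {
    abort("`hypoxia_distances_um` is empty.",
          class = "vasckill_validation_error")
  }
  if (any(!is.finite(hypoxia_distances_um)) ||
      any(hypoxia_distances_um <= 0)) {
    abort("`hypoxia_distances_um` must be positive.",
          class = "vasckill_validation_error")
  }
  check_number(o2_halving, "o2_halving", 0, Inf, allow_boundary = FALSE)
  d <- hypoxia_distances_um
  tibble(
    mean_um = o2_halving * mean(d),
    sd_um = o2_halving * (if (length(d) > 1L) sd(d) else 0),
    n = length(d)
  )
}

#' Reference IHC marker summary table
#'
#' The package's built-in per-group marker averages (mean stain fraction,
#' SD and the marker panel) for the two murine lymphoma lines, treated and
#' untreated: necrosis (H&E), apoptosis (Caspase-3), vessels (CD31),
#' hypoxia (HIF-1\eqn{\alpha}) and proliferation (Ki-67). These are the
#' defaults the synthetic generator draws groups from and the anchors for
#' the treated/untreated fold-change checks.
#'
#' @return A tibble with columns `marker`, `line`, `treated`,
#'   `mean_fraction`, `sd_fraction`.
#' @examples
#' marker_reference()
#' @export
marker_reference <- function() {
  tibble::tribble(
    ~marker,     ~line,        ~treated, ~mean_fraction, ~sd_fraction,
    "necrosis",  "sensitive",  TRUE,     0.121,          0.05,
    "necrosis",  "resistant",  TRUE,     0.047,          0.03,
    "necrosis",  "sensitive",  FALSE,    0.005,          0.00,
    "necrosis",  "resistant",  FALSE,    0.008,          0.01,
    "apoptosis", "sensitive",  TRUE,     0.038,          0.02,
    "apoptosis", "resistant",  TRUE,     0.051,          0.03,
    "apoptosis", "sensitive",  FALSE,    0.048,          0.02,
    "apoptosis", "resistant",  FALSE,    0.207,          0.12,
    "cd31",      "sensitive",  TRUE,     0.031,          0.02,
    "cd31",      "resistant",  TRUE,     0.045,          0.03,
    "cd31",      "sensitive",  FALSE,    0.018,          0.01,
    "cd31",      "resistant",  FALSE,    0.028,          0.02,
    "hif1a",     "sensitive",  TRUE,     0.133,          0.08,
    "hif1a",     "resistant",  TRUE,     0.134,          0.06,
    "hif1a",     "sensitive",  FALSE,    0.017,          0.01,
    "hif1a",     "resistant",  FALSE,    0.034,          0.04,
    "ki67",      "sensitive",  TRUE,     0.736,          0.13,
    "ki67",      "resistant",  TRUE,     0.870,          0.06,
    "ki67",      "sensitive",  FALSE,    0.772,          0.18,
    "ki67",      "resistant",  FALSE,    0.753,          0.14
  )
}
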