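# Readers for the pipeline's CSV schemas. Percent-vs-fraction: files may
# carry either convention; the reader normalizes everything to fractions.

convert_convention <- function(x, convention) {
  if (convention == "percent") x / 100 else x
}

#' Read a per-ROI stain measurement table
#'
#' Expects columns `line`, `treated`, `section_index`, `roi_index`,
#' `marker`, `stained_area`, `total_area`. Areas are pixel counts, not
#' fractions, so no convention applies.
#'
#' @param path Path to `sections.csv`.
#' @return A tibble.
#' @export
read_sections <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("line", "treated", "section_index", "roi_index",
                      "marker", "stained_area", "total_area"), path)
  df
}

#' Read a vessel cross-section table
#'
#' Expects columns `line`, `section_index`, `vessel_id`, `extent1_um`,
#' `extent2_um`, `vessel_class`.
#'
#' @param path Path to `vessels.csv`.
#' @return A tibble.
#' @export
read_vessels <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("line", "section_index", "extent1_um", "extent2_um"),
                path)
  df
}

#' Read a per-section kill dataset
#'
#' Expects columns `line`, `section_index`, `bvf`, `dead_fraction`.
#'
#' @param path Path to `killdata.csv`.
#' @param convention `"fraction"` (default) if `bvf` and `dead_fraction`
#'   are already fractions; `"percent"` if they are percentages, in which
#'   case they are divided by 100 on read.
#' @return A tibble with attribute `rescaled = FALSE`.
#' @export
read_kill_data <- function(path, convention = c("fraction", "percent")) {
  convention <- match.arg(convention)
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("line", "section_index", "bvf", "dead_fraction"),
                path)
  df <- df |>
    dplyr::mutate(
      bvf = convert_convention(.data$bvf, convention),
      dead_fraction = convert_convention(.data$dead_fraction, convention))
  attr(df, "rescaled") <- FALSE
  df
}

#' Read a dose-response table
#'
#' Expects columns `line`, `concentration_nM`, `viability_fraction`,
#' `replicate`.
#'
#' @param path Path to `doseresponse.csv`.
#' @return A tibble.
#' @export
read_dose_response <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("line", "concentration_nM", "viability_fraction"),
                path)
  df
}

#' Validate pipeline input tables
#'
#' Schema and invariant checks for the CSV inputs, distinguishing warnings
#' from errors. Checks include: required columns, stained area not
#' exceeding total area, `bvf`/`dead_fraction` within \[0, 1\] under the
#' declared convention, and a convention-mismatch heuristic (fraction-
#' convention columns with values > 1.5 are flagged as probable
#' percentages).
#'
#' @param paths Named list/character of file paths; recognized names are
#'   `sections`, `vessels`, `killdata`, `doseresponse` (any subset).
#' @param convention Declared convention for the kill data.
#' @return A tibble with columns `file`, `row`, `column`, `severity`
#'   (`"error"` or `"warning"`) and `message`; zero rows when everything
#'   is clean. The number of errors is attached as attribute `n_errors`.
#' @export
validate_inputs <- function(paths, convention = c("fraction", "percent")) {
  convention <- match.arg(convention)
  issues <- list()
  note <- function(file, row, column, severity, message) {
    issues[[length(issues) + 1L]] <<-
      tibble(file = file, row = row, column = column,
             severity = severity, message = message)
  }
  read_or_note <- function(name, reader, ...) {
    if (is.null(paths[[name]])) return(NULL)
    tryCatch(reader(paths[[name]], ...), error = function(e) {
      note(name, NA_integer_, NA_character_, "error", conditionMessage(e))
      NULL
    })
  }
  sections <- read_or_note("sections", read_sections)
  if (!is.null(sections)) {
    bad <- which(sections$stained_area > sections$total_area)
    for (i in bad) {
      note("sections", i, "stained_area", "error",
           "stained_area exceeds total_area")
    }
    bad <- which(sections$total_area <= 0)
    for (i in bad) {
      note("sections", i, "total_area", "error", "total_area must be > 0")
    }
  }
  vessels <- read_or_note("vessels", read_vessels)
  if (!is.null(vessels)) {
    bad <- which(vessels$extent1_um <= 0 | vessels$extent2_um <= 0)
    for (i in bad) {
      note("vessels", i, "extent1_um/extent2_um", "error",
           "vessel extents must be positive")
    }
  }
  kill <- if (!is.null(paths[["killdata"]])) {
    tryCatch(readr::read_csv(paths[["killdata"]], show_col_types = FALSE),
             error = function(e) {
               note("killdata", NA_integer_, NA_character_, "error",
                    conditionMessage(e))
               NULL
             })
  }
  if (!is.null(kill)) {
    missing_cols <- setdiff(c("line", "section_index", "bvf",
                              "dead_fraction"), names(kill))
    if (length(missing_cols) > 0L) {
      note("killdata", NA_integer_, paste(missing_cols, collapse = ","),
           "error", "missing required column(s)")
    } else {
      for (col in c("bvf", "dead_fraction")) {
        v <- kill[[col]]
        if (convention == "fraction" && any(v > 1.5, na.rm = TRUE)) {
          note("killdata", NA_integer_, col, "warning",
               "values > 1.5 under fraction convention; percentages supplied?")
        }
        vv <- convert_convention(v, convention)
        bad <- which(vv < 0 | vv > 1)
        for (i in bad) {
          note("killdata", i, col, "error",
               "value outside [0, 1] after convention conversion")
        }
      }
    }
  }
  out <- if (length(issues) == 0L) {
    tibble(file = character(), row = integer(), column = character(),
           severity = character(), message = character())
  } else {
    dplyr::bind_rows(issues)
  }
  attr(out, "n_errors") <- sum(out$severity == "error")
  out
}
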