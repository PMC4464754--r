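# End-to-end orchestration: simulate (or read) inputs, summarize histology,
# estimate parameters, calibrate, predict, rank sensitivities, and write a
# diff-able report bundle (CSV + JSON) with a run manifest.

default_run_config <- function() {
  list(
    synthetic = TRUE,
    seed = 1L,
    convention = "fraction",
    paths = list(sections = NULL, vessels = NULL, killdata = NULL,
                 doseresponse = NULL),
    rescale_factor = 3.5,
    L_um = 40,
    fit = list(init = list(fkill_m = 0.2, rb_over_L = 0.1),
               bounds = list(rb_over_L = c(1e-3, 2), fkill_m = c(0, 1)),
               multistart = 10L, seed = 1L),
    sensitivity = list(deltas = c(0.01, 0.1, 0.25),
                       parameters = c("bvf", "rb_um", "L_um", "fkill_m")),
    synthetic_config = list(),
    out_dir = NULL
  )
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort("`config` must be a list or a path to a YAML file.",
          class = "vasckill_validation_error")
  }
  cfg <- modifyList(default_run_config(), config)
  if (is.null(cfg$out_dir)) {
    abort("`out_dir` must be set in the run config.",
          class = "vasckill_validation_error")
  }
  cfg
}

write_result_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}

#' Run the full analysis pipeline
#'
#' Orchestrates the workflow: simulate synthetic inputs (or read CSVs),
#' summarize the IHC markers, estimate the vascular parameters (BVF per
#' line from CD31, \eqn{r_b} from vessel cross-sections, \eqn{L} from
#' config), rescale and calibrate the kill model, tabulate the predicted
#' kill-versus-BVF curve, run the sensitivity ranking around the
#' calibrated model, and write everything plus a run manifest to
#' `out_dir`.
#'
#' @param config A named list or path to a YAML file. Recognized fields
#'   (all optional except `out_dir`): `synthetic` (logical; default TRUE),
#'   `seed`, `convention` (`"fraction"`/`"percent"`), `paths` (named list
#'   of input CSVs when `synthetic = FALSE`), `rescale_factor` (default
#'   3.5), `L_um` (penetration distance used for sensitivity references;
#'   default 40), `fit` (`init`, `bounds`, `multistart`, `seed`),
#'   `sensitivity` (`deltas`, `parameters`), `synthetic_config` (overrides
#'   passed to [synthetic_config()]), `out_dir`.
#' @return Invisibly, a list with the marker summaries, estimated
#'   parameters, the `kill_fit`, the predicted curve, the sensitivity
#'   ranking and the manifest. Files written: `marker_summaries.csv`,
#'   `estimated_parameters.json`, `killdata_rescaled.csv`,
#'   `calibration.json`, `predicted_curve.csv`, `sensitivity.csv`,
#'   `sensitivity_ranking.json`, `manifest.json`.
#' @examples
#' \donttest{
#' out <- run_pipeline(list(out_dir = tempfile("run")))
#' out$calibration$r_squared
#' }
#' @export
run_pipeline <- function(config) {
  cfg <- load_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("vasckill")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    input_checksums = list(),
    stages_completed = character()
  )
  finish_stage <- function(name) {
    manifest$stages_completed <<- c(manifest$stages_completed, name)
  }
  persist_manifest <- function() {
    write_result_json(manifest, file.path(cfg$out_dir, "manifest.json"))
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      persist_manifest()
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "vasckill_pipeline_error")
    })
  }

  # --- inputs -------------------------------------------------------------
  inputs <- run_stage("inputs", {
    if (isTRUE(cfg$synthetic)) {
      scfg <- do.call(synthetic_config,
                      modifyList(list(seed = cfg$seed),
                                 cfg$synthetic_config))
      secs <- generate_sections(scfg)
      kill <- generate_kill_dataset(scfg)
      list(sections = secs$sections, vessels = secs$vessels,
           killdata = kill$data, truth = kill$truth)
    } else {
      paths <- purrr::compact(cfg$paths)
      report <- validate_inputs(paths, cfg$convention)
      if (attr(report, "n_errors") > 0L) {
        abort(paste("input validation found errors; run validate_inputs()",
                    "for the report"))
      }
      manifest$input_checksums <<-
        as.list(tools::md5sum(unlist(paths)))
      list(
        sections = if (!is.null(paths$sections))
          read_sections(paths$sections),
        vessels = if (!is.null(paths$vessels)) read_vessels(paths$vessels),
        killdata = read_kill_data(paths$killdata, cfg$convention),
        truth = NULL)
    }
  })
  finish_stage("inputs")

  # --- histology summaries ------------------------------------------------
  summaries <- run_stage("summarize", {
    if (is.null(inputs$sections)) return(NULL)
    s <- summarize_markers(inputs$sections)
    readr::write_csv(s, file.path(cfg$out_dir, "marker_summaries.csv"))
    s
  })
  finish_stage("summarize")

  params_est <- run_stage("estimate_parameters", {
    est <- list(L_um = cfg$L_um)
    if (!is.null(summaries)) {
      cd31 <- summaries |>
        dplyr::filter(.data$marker == "cd31", .data$treated)
      est$bvf <- setNames(
        purrr::map_dbl(cd31$mean_fraction, estimate_bvf), cd31$line)
    }
    if (!is.null(inputs$vessels)) {
      rb <- estimate_vessel_radius(inputs$vessels)
      est$rb_um <- rb$mean_um
      est$rb_sd_um <- rb$sd_um
    }
    write_result_json(est, file.path(cfg$out_dir,
                                     "estimated_parameters.json"))
    est
  })
  finish_stage("estimate_parameters")

  # --- calibration --------------------------------------------------------
  fit <- run_stage("calibrate", {
    rescaled <- rescale_resistant(inputs$killdata, cfg$rescale_factor)
    readr::write_csv(rescaled,
                     file.path(cfg$out_dir, "killdata_rescaled.csv"))
    fit <- fit_kill_model(rescaled, init = cfg$fit$init,
                          bounds = cfg$fit$bounds,
                          multistart = cfg$fit$multistart,
                          seed = cfg$fit$seed)
    write_result_json(
      list(fkill_m_hat = fit$fkill_m_hat,
           rb_over_L_hat = fit$rb_over_L_hat,
           r_squared = fit$r_squared,
           residuals = fit$residuals,
           iterations = fit$iterations,
           converged = fit$converged,
           covariance = fit$covariance,
           config = list(rescale_factor = cfg$rescale_factor,
                         fit = cfg$fit)),
      file.path(cfg$out_dir, "calibration.json"))
    fit
  })
  finish_stage("calibrate")

  curve <- run_stage("predict", {
    grid <- seq(0.005, 0.2, by = 0.005)
    curve <- predict_curve(fit$fkill_m_hat, fit$rb_over_L_hat, grid)
    readr::write_csv(curve, file.path(cfg$out_dir, "predicted_curve.csv"))
    curve
  })
  finish_stage("predict")

  # --- sensitivity around the calibrated model ----------------------------
  sens <- run_stage("sensitivity", {
    rb_um <- params_est$rb_um %||% 5
    L_um <- rb_um / fit$rb_over_L_hat
    bvf_ref <- if (!is.null(params_est$bvf)) mean(params_est$bvf)
               else mean(inputs$killdata$bvf)
    reference <- model_params(bvf_ref, rb_um, L_um,
                              max(fit$fkill_m_hat, 1e-6))
    ranking <- sensitivity_ranking(reference,
                                   parameters = cfg$sensitivity$parameters,
                                   deltas = cfg$sensitivity$deltas)
    readr::write_csv(attr(ranking, "coefficients"),
                     file.path(cfg$out_dir, "sensitivity.csv"))
    write_result_json(
      list(reference = reference[c("bvf", "rb_um", "L_um", "fkill_m")],
           ranking = as.list(setNames(ranking$mean_abs_S,
                                      ranking$parameter))),
      file.path(cfg$out_dir, "sensitivity_ranking.json"))
    ranking
  })
  finish_stage("sensitivity")

  persist_manifest()
  invisible(list(marker_summaries = summaries,
                 estimated_parameters = params_est,
                 calibration = fit, predicted_curve = curve,
                 sensitivity_ranking = sens, manifest = manifest))
}
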