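# End-to-end orchestration: read -> media correction -> OD calibration ->
# emission-ratio fit -> chosen estimator(s) -> tabular outputs.

#' Build a pipeline run configuration
#'
#' @param data Path to the data CSV (see [read_plate_csv()]).
#' @param layout Path to the layout CSV.
#' @param calibration Optional path to a dilution-series CSV with columns
#'   `od`, `dilution_factor`; without it relative density falls back to raw
#'   OD (with a warning).
#' @param method One of `"direct"`, `"bayes"`, `"subtraction"`, `"all"`.
#' @param n_ra,n_g,noise_window,seed Sampler settings for the Bayesian
#'   estimator (see [bayes_pipeline()]).
#' @param rg Reporter emission ratio (default EGFP, 0.114).
#' @param outdir Output directory; created if absent.
#' @return A validated list of class `run_config`.
#' @export
pipeline_config <- function(data, layout, calibration = NULL,
                            method = c("all", "direct", "bayes", "subtraction"),
                            n_ra = 50, n_g = 1000, noise_window = 20,
                            seed = 1L, rg = 0.114, outdir = "platemix-out") {
  method <- match.arg(method)
  for (p in c(data, layout, calibration)) {
    if (!is.null(p) && !file.exists(p)) {
      stop_platemix(paste("file not found:", p), "platemix_validation_error")
    }
  }
  structure(list(data = data, layout = layout, calibration = calibration,
                 method = method, n_ra = n_ra, n_g = n_g,
                 noise_window = noise_window, seed = as.integer(seed),
                 rg = rg, outdir = outdir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes read, media correction, OD calibration (or the identity
#' fallback), emission-ratio estimation, and the configured estimator(s), and
#' writes three files to `config$outdir`: `results.csv` (the per-cell
#' fluorescence table, schema `strain, condition, time_h, fl_per_cell_mean,
#' fl_per_cell_sd, n_replicates, method`), `qc.csv` (negative-value counts
#' after media correction), and `manifest.json` (configuration, seed, and
#' package version — enough to reproduce the run).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the estimates (`direct`, `bayes`,
#'   `subtraction` as configured), the fitted `media`, `cal`, `ra` objects,
#'   and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dataset <- read_plate_csv(config$data, config$layout)
  mc <- fit_media(dataset)
  corrected <- apply_media_correction(dataset, mc)

  cal <- if (!is.null(config$calibration)) {
    tab <- utils::read.csv(config$calibration)
    if (!all(c("od", "dilution_factor") %in% names(tab))) {
      stop_platemix("calibration CSV needs columns od, dilution_factor",
                    "platemix_schema_error")
    }
    fit_od_calibration(tab$od, tab$dilution_factor)
  } else {
    identity_calibration(range(corrected$od))
  }

  constants <- unmixing_constants(config$rg)
  methods <- if (config$method == "all") c("direct", "bayes", "subtraction") else config$method
  ra <- if (any(methods %in% c("direct", "bayes"))) fit_ra(corrected) else NULL

  est <- list()
  if ("direct" %in% methods) {
    est$direct <- direct_pipeline(corrected, cal, constants)
  }
  if ("bayes" %in% methods) {
    est$bayes <- bayes_pipeline(corrected, ra, cal, constants,
                                n_ra = config$n_ra, n_g = config$n_g,
                                seed = config$seed,
                                noise_window = config$noise_window)
  }
  if ("subtraction" %in% methods) {
    est$subtraction <- subtraction_baseline(corrected, cal)
  }

  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  results <- do.call(rbind, unlist(lapply(est, function(groups) {
    lapply(groups, as.data.frame)
  }), recursive = FALSE))
  results_path <- file.path(config$outdir, "results.csv")
  utils::write.csv(results, results_path, row.names = FALSE)

  qc <- corrected$meta$qc_negative
  qc_df <- do.call(rbind, lapply(names(qc), function(ch) {
    data.frame(well = names(qc[[ch]]), channel = ch,
               n_negative_after_correction = as.integer(qc[[ch]]))
  }))
  qc_path <- file.path(config$outdir, "qc.csv")
  utils::write.csv(qc_df, qc_path, row.names = FALSE)

  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(
    list(config = unclass(config),
         media_mode = as.list(mc$mode_used),
         package_version = as.character(utils::packageVersion("platemix"))),
    manifest_path, auto_unbox = TRUE, pretty = TRUE, null = "null")

  invisible(list(estimates = est, media = mc, cal = cal, ra = ra,
                 dataset = corrected,
                 paths = list(results = results_path, qc = qc_path,
                              manifest = manifest_path)))
}

#' Simulate a plate experiment to disk
#'
#' Writes the data CSV, layout CSV, and a ground-truth CSV (aligned
#' row-for-row with the data CSV) for a synthetic scenario, ready to be
#' analysed with [run_pipeline()].
#'
#' @param scenario A [synthetic_scenario()].
#' @param outdir Output directory.
#' @param ... Passed on to [generate_experiment()].
#' @return Invisibly, the list of written paths.
#' @export
simulate_to_files <- function(scenario = synthetic_scenario(),
                              outdir = "platemix-sim", ...) {
  sim <- generate_experiment(scenario, ...)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  data_path <- file.path(outdir, "data.csv")
  layout_path <- file.path(outdir, "layout.csv")
  write_plate_csv(sim$dataset, data_path, layout_path)
  wells <- colnames(sim$dataset$od)
  truth <- do.call(rbind, lapply(wells, function(w) {
    tw <- sim$truth$wells[[w]]
    data.frame(well = w, time_h = sim$truth$times,
               density = tw$density, a = tw$a, g = tw$g,
               per_cell = tw$per_cell, stringsAsFactors = FALSE)
  }))
  truth_path <- file.path(outdir, "truth.csv")
  utils::write.csv(truth, truth_path, row.names = FALSE)
  invisible(list(data = data_path, layout = layout_path, truth = truth_path))
}
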