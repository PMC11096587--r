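# End-to-end pipeline entry points backing the command-line script in
# inst/cli/t2dmarkov.R: forecast with extreme bounds, validation against an
# observed series, and synthetic-data generation, each writing tidy result
# files plus a run manifest.

run_manifest <- function(inputs, seed = NA_integer_) {
  list(
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    seed = seed,
    package_version = as.character(utils::packageVersion("t2dmarkov")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

#' Forecast pipeline: baseline (and scenario) runs with extreme bounds
#'
#' Reads the population and prevalence CSVs, runs the model at central,
#' all-minimum and all-maximum parameter values (optionally under a
#' scenario), and writes a tidy bounds CSV
#' (`year,sex,metric,central,min,max`), a JSON summary for the anchor
#' years, and a run manifest.
#'
#' @param population_csv,prevalence_csv Input table paths (the prevalence
#'   file is expected in percent, as printed).
#' @param scenario_yaml Optional scenario YAML path.
#' @param out_dir Output directory (created if missing).
#' @param params A [risk_params()].
#' @param config A [model_config()].
#' @return Invisibly, a list with the bounds table and output paths.
#' @export
cmd_forecast <- function(population_csv, prevalence_csv, scenario_yaml = NULL,
                         out_dir = ".", params = risk_params(),
                         config = model_config()) {
  for (p in c(population_csv, prevalence_csv, scenario_yaml)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  pop <- read_age_sex_table(population_csv, "population_millions")
  prev <- read_age_sex_table(prevalence_csv, "prevalence_fraction",
                             units = "percent")
  scenario <- if (!is.null(scenario_yaml)) read_scenario(scenario_yaml)
  bounds <- extreme_bounds(function(set) {
    run_markov(pop, prev, params, config, scenario, param_set = set)
  })
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  label <- if (is.null(scenario)) "baseline" else scenario$name
  csv_path <- file.path(out_dir, paste0("forecast_", label, ".csv"))
  write_forecast_csv(bounds, csv_path)
  anchor_years <- intersect(c(config$start_year, 2020L, config$end_year),
                            unique(bounds$year))
  summary <- lapply(anchor_years, function(y) {
    sub <- bounds[bounds$year == y & bounds$metric == "prevalence", ]
    stats::setNames(lapply(sub$sex, function(s) {
      r <- sub[sub$sex == s, ]
      list(central = r$central, min = r$min, max = r$max)
    }), sub$sex)
  })
  names(summary) <- anchor_years
  json_path <- file.path(out_dir, paste0("forecast_", label, ".json"))
  jsonlite::write_json(list(scenario = label, prevalence = summary,
                            manifest = run_manifest(c(population_csv, prevalence_csv,
                                                      scenario_yaml))),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(bounds = bounds, csv = csv_path, json = json_path))
}

#' Validation pipeline: model vs observed series
#'
#' Runs the central model and compares it year by year with the observed
#' (corrected) prevalence series, writing a per-year report CSV.
#'
#' @inheritParams cmd_forecast
#' @param correction_factor Multiplier applied to the observed
#'   self-reported series (default 1.5; 1.0 compares raw values).
#' @return Invisibly, the validation data frame (attribute `mae` holds
#'   the mean absolute error).
#' @export
cmd_validate <- function(population_csv, prevalence_csv, out_dir = ".",
                         correction_factor = 1.5, params = risk_params(),
                         config = model_config()) {
  for (p in c(population_csv, prevalence_csv)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  pop <- read_age_sex_table(population_csv, "population_millions")
  prev <- read_age_sex_table(prevalence_csv, "prevalence_fraction",
                             units = "percent")
  result <- run_markov(pop, prev, params, config)
  report <- validate_series(result, prev, pop, factor = correction_factor)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, "validation.csv")
  utils::write.csv(report, path, row.names = FALSE)
  invisible(report)
}

#' Synthetic-data pipeline
#'
#' Writes a synthetic prevalence panel and population projection in the
#' same CSV dialect the readers consume (prevalence in percent).
#'
#' @param out_dir Output directory.
#' @param spec A [synthetic_spec()].
#' @return Invisibly, the two output paths.
#' @export
cmd_synth <- function(out_dir = ".", spec = synthetic_spec()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prev <- generate_prevalence_panel(spec)
  prev$value <- prev$value * 100  # write in percent, as surveys publish
  prev_path <- file.path(out_dir, "synthetic_prevalence.csv")
  utils::write.csv(as.data.frame(prev), prev_path, row.names = FALSE)
  pop <- generate_population_projection(spec)
  pop_path <- file.path(out_dir, "synthetic_population.csv")
  write_age_sex_table(pop, pop_path)
  invisible(c(prevalence = prev_path, population = pop_path))
}
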