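# Synthetic inputs with known ground truth: an annual telephone-survey-like
# prevalence panel (linear latent trends + binomial sampling noise) and a
# deterministic cohort population projection. Every generator is a pure
# function of its spec (the RNG state is restored on exit).

default_latent <- function() {
  m <- function(...) {
    out <- matrix(c(...), nrow = 2, byrow = TRUE,
                  dimnames = list(SEXES, AGE_BANDS))
    out
  }
  list(
    t2d = list(
      intercept = m(0.013, 0.026, 0.070, 0.126, 0.169, 0.183,
                    0.010, 0.024, 0.059, 0.135, 0.184, 0.177),
      slope = m(0.0003, 0.0006, 0.0007, 0.0023, 0.0041, 0.0045,
                0.0009, 0.0010, 0.0014, 0.0018, 0.0031, 0.0036)),
    obesity = list(
      intercept = m(0.122, 0.155, 0.173, 0.161, 0.132, 0.089,
                    0.071, 0.105, 0.148, 0.190, 0.190, 0.183),
      slope = m(0.0056, 0.0074, 0.0059, 0.0059, 0.0046, 0.0038,
                0.0078, 0.0085, 0.0059, 0.0032, 0.0034, 0.0018)),
    smoking = list(
      intercept = m(0.167, 0.175, 0.226, 0.185, 0.138, 0.083,
                    0.084, 0.124, 0.176, 0.113, 0.078, 0.054),
      slope = m(-0.0028, -0.0044, -0.0053, -0.0022, -0.0019, -0.0013,
                -0.0021, -0.0036, -0.0044, -0.0005, -0.0010, -0.0007))
  )
}

default_pop_base <- function() {
  matrix(c(15.6, 12.7, 9.6, 5.8, 3.2, 1.7,
           15.5, 13.0, 10.1, 6.5, 3.9, 2.6),
         nrow = 2, byrow = TRUE, dimnames = list(SEXES, AGE_BANDS))
}

default_pop_growth <- function() {
  matrix(c(0.009, 0.016, 0.020, 0.037, 0.042, 0.046,
           0.007, 0.018, 0.021, 0.037, 0.042, 0.044),
         nrow = 2, byrow = TRUE, dimnames = list(SEXES, AGE_BANDS))
}

#' Specification for the synthetic-data generators
#'
#' Defines the latent linear prevalence trends per (factor, sex, band),
#' the survey sample size driving binomial observation noise, and the
#' per-band exponential population growth. Defaults emulate a
#' middle-income-country panel: rising diabetes and obesity, falling
#' smoking, faster growth in the older bands (population aging), and
#' 5,000 respondents per cell per survey year.
#'
#' @param seed RNG seed; all draws are reproducible under it.
#' @param years Survey years of the panel.
#' @param survey_n Respondents per (year, sex, band) cell (> 0).
#' @param latent Nested list per factor (`t2d`, `obesity`, `smoking`) of
#'   `intercept` and `slope` matrices (sex x band); intercepts are latent
#'   prevalences at the first year, slopes in fraction/yr.
#' @param pop_base,pop_growth Sex x band matrices: population (millions)
#'   at the first year and exponential growth rates per year.
#' @param params True [risk_params()] used by the ground-truth harness.
#' @return List with class `synthetic_spec`. Latent prevalences are
#'   validated to stay inside \[0, 1\] over `years`.
#' @export
synthetic_spec <- function(seed = 1L, years = 2006:2020, survey_n = 5000,
                           latent = default_latent(),
                           pop_base = default_pop_base(),
                           pop_growth = default_pop_growth(),
                           params = risk_params()) {
  if (survey_n <= 0) stop("synthetic_spec: survey_n must be > 0")
  for (fac in names(latent)) {
    for (y in range(years)) {
      p <- latent[[fac]]$intercept + latent[[fac]]$slope * (y - min(years))
      if (any(p < 0 | p > 1)) {
        stop("synthetic_spec: latent ", fac, " prevalence leaves [0, 1] at ", y)
      }
    }
  }
  if (any(pop_base * (1 + pop_growth)^(max(years) - min(years)) <= 0)) {
    stop("synthetic_spec: growth drives population non-positive")
  }
  structure(list(seed = as.integer(seed), years = as.integer(years),
                 survey_n = survey_n, latent = latent,
                 pop_base = pop_base, pop_growth = pop_growth,
                 params = params),
            class = "synthetic_spec")
}

#' Latent (noise-free) prevalence under a synthetic spec
#'
#' @param spec A [synthetic_spec()].
#' @param factor,sex,band Cell coordinates.
#' @param year Calendar year.
#' @return Latent prevalence fraction.
#' @export
latent_prevalence <- function(spec, factor, sex, band, year) {
  l <- spec$latent[[factor]]
  unname(l$intercept[sex, band] + l$slope[sex, band] * (year - min(spec$years)))
}

with_spec_seed <- function(spec, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)
  force(expr)
}

#' Generate a survey-like prevalence panel
#'
#' Observed prevalence per cell is
#' `Binomial(survey_n, latent_p) / survey_n` — the sampling noise of a
#' simple random telephone survey (design effects and weighting are not
#' emulated). With `noise = FALSE` the latent values are returned exactly.
#'
#' @param spec A [synthetic_spec()].
#' @param noise Draw binomial noise (default) or return latent values.
#' @return A prevalence [age_sex_table()] with a `factor` column.
#' @export
generate_prevalence_panel <- function(spec, noise = TRUE) {
  grid <- expand.grid(year = spec$years, sex = SEXES, age_band = AGE_BANDS,
                      factor = names(spec$latent),
                      stringsAsFactors = FALSE)
  grid$value <- mapply(function(f, s, b, y) latent_prevalence(spec, f, s, b, y),
                       grid$factor, grid$sex, grid$age_band, grid$year)
  if (noise) {
    grid$value <- with_spec_seed(spec, {
      stats::rbinom(nrow(grid), spec$survey_n, grid$value) / spec$survey_n
    })
  }
  age_sex_table(grid, "prevalence_fraction")
}

#' Generate a cohort-style population projection
#'
#' Deterministic exponential growth per (sex, band):
#' `P(y) = base * (1 + growth)^(y - y0)`. Faster growth in older bands
#' shifts the age structure upward over time, mimicking demographic aging.
#'
#' @param spec A [synthetic_spec()].
#' @param years Years to tabulate (default the spec's survey years).
#' @return A population [age_sex_table()] (millions).
#' @export
generate_population_projection <- function(spec, years = spec$years) {
  grid <- expand.grid(year = years, sex = SEXES, age_band = AGE_BANDS,
                      stringsAsFactors = FALSE)
  grid$value <- mapply(function(s, b, y) {
    spec$pop_base[s, b] * (1 + spec$pop_growth[s, b])^(y - min(spec$years))
  }, grid$sex, grid$age_band, grid$year)
  age_sex_table(grid, "population_millions")
}

#' Noiseless reference run for recovery experiments
#'
#' Builds exact (noise-free) inputs from the spec, runs the full engine,
#' and returns both the inputs and the reference forecast. Test harnesses
#' perturb the prevalence panel with survey noise and check how closely
#' the pipeline recovers this reference.
#'
#' @param spec A [synthetic_spec()].
#' @param config A [model_config()]; its horizon must extend past the
#'   panel years.
#' @return List: `population`, `prevalence` (noiseless), `reference`
#'   (a `forecast_result`).
#' @export
generate_ground_truth_run <- function(spec,
                                      config = model_config(
                                        start_year = min(spec$years),
                                        end_year = max(spec$years) + 16L,
                                        calibration_year = min(spec$years) + 4L)) {
  prev <- generate_prevalence_panel(spec, noise = FALSE)
  pop_years <- config$start_year:config$end_year
  pop <- generate_population_projection(spec, years = pop_years)
  reference <- run_markov(pop, prev, spec$params, config)
  list(population = pop, prevalence = prev, reference = reference)
}
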