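# Risk-factor trend estimation and projection: pooled OLS with age-band
# fixed effects and a shared calendar-time slope, plus policy-scenario
# modification of the obesity path.

#' Fit a pooled linear trend to one risk factor and sex
#'
#' Ordinary least squares of prevalence on calendar year pooled over the
#' six age bands: per-band intercepts (fixed effects) and one shared slope
#' in prevalence fraction per year. Pooling the bands increases the
#' information available for the common time effect. An independent
#' per-band-slopes variant is available for sensitivity.
#'
#' @param panel An [age_sex_table()] of prevalence fractions (optionally
#'   with a `factor` column).
#' @param factor Factor label to restrict to, if the panel has several.
#' @param sex `"M"` or `"W"`.
#' @param pooled If `FALSE`, fit an independent slope per band instead of
#'   a shared one.
#' @return A `trend_model`: list with `factor`, `sex`, `slope` (per-band
#'   named vector; identical entries when pooled), `intercepts` (per-band,
#'   at `year = fit_window[1]`), `fit_window` and the fitted `lm` object.
#' @export
fit_pooled_trend <- function(panel, factor = NULL, sex, pooled = TRUE) {
  df <- as.data.frame(panel)
  if (!is.null(factor)) {
    if (!"factor" %in% names(df)) stop("fit_pooled_trend: panel has no factor column")
    df <- df[df$factor == factor, , drop = FALSE]
  }
  df <- df[df$sex == sex, , drop = FALSE]
  if (nrow(df) == 0L) stop("fit_pooled_trend: empty panel after restriction")
  years <- sort(unique(df$year))
  if (length(years) < 2L) {
    stop("fit_pooled_trend: need >= 2 distinct years (singular design)")
  }
  y0 <- min(years)
  df$t <- df$year - y0
  df$age_band <- base::factor(df$age_band, levels = AGE_BANDS)
  if (pooled) {
    fit <- stats::lm(value ~ 0 + age_band + t, data = df)
    slope <- rep(unname(stats::coef(fit)["t"]), length(AGE_BANDS))
  } else {
    fit <- stats::lm(value ~ 0 + age_band + age_band:t, data = df)
    cf <- stats::coef(fit)
    slope <- unname(cf[paste0("age_band", AGE_BANDS, ":t")])
  }
  intercepts <- unname(stats::coef(fit)[paste0("age_band", AGE_BANDS)])
  structure(list(factor = factor, sex = sex,
                 slope = stats::setNames(slope, AGE_BANDS),
                 intercepts = stats::setNames(intercepts, AGE_BANDS),
                 fit_window = c(y0, max(years)),
                 fit = fit, pooled = pooled),
            class = "trend_model")
}

#' @export
print.trend_model <- function(x, ...) {
  cat("Linear prevalence trend (", if (x$pooled) "pooled slope" else "per-band slopes",
      ")\n", sep = "")
  cat("  factor:", x$factor %||% "<single>", " sex:", x$sex, "\n")
  cat("  window:", x$fit_window[1], "-", x$fit_window[2], "\n")
  cat("  slope (pp/yr):", round(100 * x$slope[1], 3), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Project a fitted trend to a year
#'
#' Linear evaluation `intercept_band + slope * (year - window_start)`,
#' clamped to \[0, 1\]. Clamping is reported via an attribute so callers
#' can log it (smoking prevalence projects to near zero in some bands).
#'
#' @param trend A `trend_model` from [fit_pooled_trend()].
#' @param year Calendar year (at or after the fit window start).
#' @param band Age band label (any subset of the six; default all).
#' @return Named prevalence fractions, with attribute `clamped` flagging
#'   bands whose raw projection left \[0, 1\].
#' @export
project_trend <- function(trend, year, band = AGE_BANDS) {
  stopifnot(inherits(trend, "trend_model"))
  if (any(!band %in% AGE_BANDS)) {
    stop("project_trend: unknown band(s): ",
         paste(setdiff(band, AGE_BANDS), collapse = ", "))
  }
  if (year < trend$fit_window[1]) {
    stop("project_trend: year precedes the fit window")
  }
  raw <- trend$intercepts[band] + trend$slope[band] * (year - trend$fit_window[1])
  out <- pmin(pmax(raw, 0), 1)
  attr(out, "clamped") <- band[raw < 0 | raw > 1]
  out
}

#' Policy scenario on the obesity path
#'
#' @param name Scenario label.
#' @param annual_change Signed per-year change: in relative mode a
#'   proportional rate (e.g. -0.01 for a 1% reduction per year), in
#'   `absolute_pp` mode a change in prevalence fraction per year.
#' @param mode `"relative"` (multiplicative `(1 + annual_change)^t` on the
#'   start-year value) or `"absolute_pp"` (arithmetic).
#' @param start_year,end_year Years over which the scenario replaces the
#'   baseline path (`start_year < end_year`).
#' @return List with class `scenario_spec`.
#' @export
scenario_spec <- function(name, annual_change,
                          mode = c("relative", "absolute_pp"),
                          start_year = 2020, end_year = 2036) {
  mode <- match.arg(mode)
  if (start_year >= end_year) stop("scenario_spec: start_year must precede end_year")
  if (mode == "relative" && annual_change <= -1) {
    stop("scenario_spec: relative annual_change must exceed -1")
  }
  structure(list(name = name, annual_change = annual_change, mode = mode,
                 start_year = as.integer(start_year),
                 end_year = as.integer(end_year),
                 target_factor = "obesity"),
            class = "scenario_spec")
}

#' Read a scenario specification from YAML
#'
#' Expected keys: `name`, `annual_change`, `mode`, `start_year`,
#' `end_year`. The packaged `scenario1.yaml` (-1%/yr, relative) and
#' `scenario2.yaml` (-5%/yr, relative) both run 2020-2036.
#'
#' @param path YAML file path.
#' @return A [scenario_spec()].
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  scenario_spec(y$name, y$annual_change, y$mode, y$start_year, y$end_year)
}

#' Apply a policy scenario to a projected path
#'
#' Years at or after `start_year` are replaced by the scenario path
#' anchored at the baseline's start-year value: relative mode compounds
#' `value(start) * (1 + annual_change)^(y - start)`; absolute mode adds
#' `annual_change * (y - start)`, floored at 0. Earlier years are left
#' untouched; results are clamped to \[0, 1\] with a warning.
#'
#' @param baseline_path Numeric vector of projected prevalences, named by
#'   year, covering `[start_year, end_year]`.
#' @param spec A [scenario_spec()].
#' @return Modified path, same names.
#' @export
apply_scenario <- function(baseline_path, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  years <- as.integer(names(baseline_path))
  if (any(is.na(years))) stop("apply_scenario: path must be named by year")
  if (!all(c(spec$start_year, spec$end_year) %in% years)) {
    stop("apply_scenario: path must cover [start_year, end_year]")
  }
  out <- baseline_path
  sel <- years >= spec$start_year
  t <- years[sel] - spec$start_year
  v0 <- baseline_path[[which(years == spec$start_year)]]
  out[sel] <- if (spec$mode == "relative") {
    v0 * (1 + spec$annual_change)^t
  } else {
    pmax(v0 + spec$annual_change * t, 0)
  }
  if (any(out < 0 | out > 1)) {
    warning("apply_scenario: path clamped to [0, 1]")
    out <- pmin(pmax(out, 0), 1)
  }
  out
}

#' Build projected risk-factor paths for the simulation horizon
#'
#' Fits pooled trends for obesity and smoking per sex on the observed
#' panel and evaluates them for every simulation year and band. An
#' optional scenario replaces the obesity path from its start year.
#'
#' @param prevalence Observed prevalence [age_sex_table()] with a `factor`
#'   column containing `"obesity"` and `"smoking"`.
#' @param years Simulation years to evaluate.
#' @param scenario Optional [scenario_spec()].
#' @param pooled Passed to [fit_pooled_trend()].
#' @return Nested list `paths[[sex]][[factor]]`: band x year matrices of
#'   prevalence fractions; also carries the fitted `trend_model`s in
#'   attribute `trends`.
#' @export
build_factor_paths <- function(prevalence, years, scenario = NULL,
                               pooled = TRUE) {
  paths <- list()
  trends <- list()
  for (s in SEXES) {
    paths[[s]] <- list()
    for (fac in c("obesity", "smoking")) {
      tr <- fit_pooled_trend(prevalence, factor = fac, sex = s, pooled = pooled)
      trends[[paste(fac, s, sep = ".")]] <- tr
      m <- matrix(NA_real_, nrow = length(AGE_BANDS), ncol = length(years),
                  dimnames = list(AGE_BANDS, years))
      for (j in seq_along(years)) {
        m[, j] <- project_trend(tr, years[j])
      }
      if (fac == "obesity" && !is.null(scenario)) {
        for (b in AGE_BANDS) {
          path <- stats::setNames(m[b, ], years)
          m[b, ] <- apply_scenario(path, scenario)
        }
      }
      paths[[s]][[fac]] <- m
    }
  }
  attr(paths, "trends") <- trends
  paths
}
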