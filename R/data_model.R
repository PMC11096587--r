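# Age-band / sex tables: the universal exchange structure of the model.
# Every input (population projection, prevalence panel) is a long data frame
# with columns year, sex, age_band, value (plus an optional factor column
# when several risk factors share one file).

#' Age bands used throughout the model
#'
#' Six contiguous ten-year bands starting at 25, the last open-ended.
#'
#' @format Character vector of band labels.
#' @export
AGE_BANDS <- c("25-34", "35-44", "45-54", "55-64", "65-74", "75+")

#' Sex labels
#' @export
SEXES <- c("M", "W")

# Lower bounds, upper bounds (Inf = open) and representative midpoints of
# the bands. The open 75+ band is assigned midpoint 82.
band_lower <- c(25, 35, 45, 55, 65, 75)
band_upper <- c(34, 44, 54, 64, 74, Inf)
band_midpoints <- c(29.5, 39.5, 49.5, 59.5, 69.5, 82)

#' Band midpoint ages
#'
#' Midpoints of the six age bands; the open-ended 75+ band is represented
#' by age 82.
#'
#' @return Named numeric vector, one midpoint per band.
#' @export
age_band_midpoints <- function() stats::setNames(band_midpoints, AGE_BANDS)

#' Construct a validated age-sex table
#'
#' @param df Data frame with columns `year`, `sex`, `age_band`, `value`
#'   and optionally `factor` (e.g. "t2d", "obesity", "smoking").
#' @param quantity Either `"population_millions"` or `"prevalence_fraction"`.
#' @return The data frame with class `age_sex_table` and a `quantity`
#'   attribute. Prevalence values must be fractions in \[0, 1\];
#'   population values must be positive.
#' @export
age_sex_table <- function(df, quantity = c("population_millions", "prevalence_fraction")) {
  quantity <- match.arg(quantity)
  needed <- c("year", "sex", "age_band", "value")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("age_sex_table: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df$year <- as.integer(df$year)
  df$value <- as.numeric(df$value)
  bad_sex <- setdiff(unique(df$sex), SEXES)
  if (length(bad_sex) > 0L) {
    stop("age_sex_table: unknown sex label(s): ", paste(bad_sex, collapse = ", "))
  }
  bad_band <- setdiff(unique(df$age_band), AGE_BANDS)
  if (length(bad_band) > 0L) {
    stop("age_sex_table: unknown age band(s): ", paste(bad_band, collapse = ", "))
  }
  if (quantity == "population_millions" && any(df$value <= 0)) {
    stop("age_sex_table: population values must be > 0")
  }
  if (quantity == "prevalence_fraction" && any(df$value < 0 | df$value > 1)) {
    stop("age_sex_table: prevalence values must lie in [0, 1]")
  }
  # every (year, sex[, factor]) slice must cover all six bands
  key <- if ("factor" %in% names(df)) {
    interaction(df$year, df$sex, df$factor, drop = TRUE)
  } else {
    interaction(df$year, df$sex, drop = TRUE)
  }
  for (k in levels(key)) {
    bands <- df$age_band[key == k]
    gap <- setdiff(AGE_BANDS, bands)
    if (length(gap) > 0L) {
      stop("age_sex_table: slice ", k, " is missing band(s): ",
           paste(gap, collapse = ", "))
    }
    if (anyDuplicated(bands)) {
      stop("age_sex_table: slice ", k, " has duplicated band(s)")
    }
  }
  structure(as.data.frame(df), class = c("age_sex_table", "data.frame"),
            quantity = quantity)
}

#' Read an age-sex table from CSV
#'
#' CSV dialect: header `year,sex,age_band,value` (optionally a `factor`
#' column), UTF-8, '.' decimal. Prevalence files printed in percent are
#' converted to fractions with `units = "percent"`.
#'
#' @param path CSV file path.
#' @param quantity `"population_millions"` or `"prevalence_fraction"`.
#' @param units For prevalence tables only: `"fraction"` (default) or
#'   `"percent"` (values divided by 100 on read).
#' @return An [age_sex_table()].
#' @export
read_age_sex_table <- function(path,
                               quantity = c("population_millions", "prevalence_fraction"),
                               units = c("fraction", "percent")) {
  quantity <- match.arg(quantity)
  units <- match.arg(units)
  if (!file.exists(path)) stop("read_age_sex_table: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("read_age_sex_table: empty table: ", path)
  if (quantity == "prevalence_fraction") {
    if (any(df$value < 0) || (units == "percent" && any(df$value > 100))) {
      stop("read_age_sex_table: prevalence outside [0, 100]")
    }
    if (units == "percent") df$value <- df$value / 100
  }
  age_sex_table(df, quantity)
}

#' Write an age-sex table to CSV
#'
#' Inverse of [read_age_sex_table()] with `units = "fraction"`; values are
#' written at full precision so read-write round-trips are exact.
#'
#' @param x An [age_sex_table()].
#' @param path Output CSV path.
#' @export
write_age_sex_table <- function(x, path) {
  stopifnot(inherits(x, "age_sex_table"))
  df <- as.data.frame(x)
  df$value <- format(df$value, digits = 17, scientific = FALSE, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract one (year, sex[, factor]) slice as a band-named vector
#'
#' @param table An [age_sex_table()].
#' @param year Calendar year.
#' @param sex `"M"` or `"W"`.
#' @param factor Optional factor label when the table has a `factor` column.
#' @return Named numeric vector over the six bands, in band order.
#' @export
ast_slice <- function(table, year, sex, factor = NULL) {
  sel <- table$year == year & table$sex == sex
  if (!is.null(factor)) {
    if (!"factor" %in% names(table)) stop("ast_slice: table has no factor column")
    sel <- sel & table$factor == factor
  }
  sub <- table[sel, , drop = FALSE]
  if (nrow(sub) != length(AGE_BANDS)) {
    stop("ast_slice: no complete slice for year=", year, " sex=", sex,
         if (!is.null(factor)) paste0(" factor=", factor))
  }
  stats::setNames(sub$value[match(AGE_BANDS, sub$age_band)], AGE_BANDS)
}

#' Years present in a table
#' @param table An [age_sex_table()].
#' @return Sorted integer vector of distinct years.
#' @export
ast_years <- function(table) sort(unique(table$year))

# Linear interpolation of a table between its anchor years, per
# (sex, band[, factor]) cell. Exact at anchors, error outside the range.
interpolate_cell <- function(years, values, year) {
  stats::approx(years, values, xout = year, method = "linear", rule = 1)$y
}

#' Interpolate an age-sex table to an arbitrary year
#'
#' The population projection (and the observed prevalence panel when only
#' anchor years are available) is interpolated linearly per (sex, band)
#' between the nearest anchor years. Exact at anchors; requesting a year
#' outside the anchor range is an error (no extrapolation).
#'
#' @param table An [age_sex_table()].
#' @param year Calendar year within the anchor range.
#' @param factor Optional factor label to restrict to.
#' @return A data frame slice (columns `year,sex,age_band,value`) for the
#'   requested year.
#' @export
interpolate_years <- function(table, year, factor = NULL) {
  yrs <- ast_years(table)
  if (year < min(yrs) || year > max(yrs)) {
    stop("interpolate_years: year ", year, " outside anchor range [",
         min(yrs), ", ", max(yrs), "]")
  }
  out <- expand.grid(sex = SEXES, age_band = AGE_BANDS,
                     stringsAsFactors = FALSE)
  out$year <- as.integer(year)
  out$value <- NA_real_
  for (i in seq_len(nrow(out))) {
    sel <- table$sex == out$sex[i] & table$age_band == out$age_band[i]
    if (!is.null(factor)) sel <- sel & table$factor == factor
    sub <- table[sel, , drop = FALSE]
    sub <- sub[order(sub$year), , drop = FALSE]
    out$value[i] <- interpolate_cell(sub$year, sub$value, year)
  }
  out[, c("year", "sex", "age_band", "value")]
}

#' Interpolate the population projection to a given year
#'
#' @param table Population [age_sex_table()] (millions).
#' @param year Calendar year within the anchors.
#' @return Slice data frame for `year`; see [interpolate_years()].
#' @export
interpolate_population <- function(table, year) {
  stopifnot(attr(table, "quantity") == "population_millions")
  interpolate_years(table, year)
}

#' Population-weighted total prevalence over the two sexes
#'
#' @param prev_m,prev_w Prevalence fractions for men and women.
#' @param pop_m,pop_w Population sizes (any common unit, e.g. millions).
#' @return `(prev_m * pop_m + prev_w * pop_w) / (pop_m + pop_w)`.
#' @export
weighted_total_prevalence <- function(prev_m, prev_w, pop_m, pop_w) {
  if (any(prev_m < 0 | prev_m > 1 | prev_w < 0 | prev_w > 1)) {
    stop("weighted_total_prevalence: prevalence outside [0, 1]")
  }
  if (any(pop_m <= 0 | pop_w <= 0)) {
    stop("weighted_total_prevalence: populations must be > 0")
  }
  (prev_m * pop_m + prev_w * pop_w) / (pop_m + pop_w)
}

# ---- epidemiological parameters -------------------------------------------

triple <- function(min, central, max, name) {
  v <- c(min = min, central = central, max = max)
  if (any(v < 0)) stop("risk_params: ", name, " must be >= 0")
  if (!(min <= central && central <= max)) {
    stop("risk_params: ", name, " must satisfy min <= central <= max")
  }
  v
}

#' Epidemiological model parameters with plausibility bounds
#'
#' Every parameter is carried as a (min, central, max) triple so the
#' extreme-value sensitivity analysis can re-run the model at the joint
#' minima and maxima. Defaults:
#' * `rr_inc_obesity` — relative risk of diabetes incidence, obese vs
#'   non-obese: (2, 3, 4), the usual range for a binary BMI > 30 exposure.
#' * `rr_inc_smoking` — relative risk of diabetes incidence, current smoker
#'   vs non-smoker: (1.3, 1.35, 1.4), i.e. 30-40% excess risk.
#' * `rr_mort_t2d` — usual relative risk of all-cause mortality, diabetic
#'   vs healthy: (1.5, 2, 2.5).
#' * `remission_rate` — fixed at (0, 0, 0); type 2 diabetes is treated as
#'   irreversible.
#' * `correction_factor` — multiplier inflating self-reported diabetes
#'   prevalence for under-diagnosis: (1.2, 1.5, 2).
#'
#' @param rr_inc_obesity,rr_inc_smoking,rr_mort_t2d,remission_rate,correction_factor
#'   Length-3 numeric vectors `(min, central, max)`.
#' @return A list of named triples with class `risk_params`.
#' @export
risk_params <- function(rr_inc_obesity = c(2, 3, 4),
                        rr_inc_smoking = c(1.3, 1.35, 1.4),
                        rr_mort_t2d = c(1.5, 2, 2.5),
                        remission_rate = c(0, 0, 0),
                        correction_factor = c(1.2, 1.5, 2)) {
  if (any(remission_rate != 0)) {
    stop("risk_params: remission_rate is fixed at zero")
  }
  p <- list(
    rr_inc_obesity = triple(rr_inc_obesity[1], rr_inc_obesity[2], rr_inc_obesity[3], "rr_inc_obesity"),
    rr_inc_smoking = triple(rr_inc_smoking[1], rr_inc_smoking[2], rr_inc_smoking[3], "rr_inc_smoking"),
    rr_mort_t2d = triple(rr_mort_t2d[1], rr_mort_t2d[2], rr_mort_t2d[3], "rr_mort_t2d"),
    remission_rate = c(min = 0, central = 0, max = 0),
    correction_factor = triple(correction_factor[1], correction_factor[2], correction_factor[3], "correction_factor")
  )
  for (nm in c("rr_inc_obesity", "rr_inc_smoking", "rr_mort_t2d", "correction_factor")) {
    if (any(p[[nm]] <= 0)) stop("risk_params: ", nm, " must be > 0")
  }
  structure(p, class = "risk_params")
}

#' Collapse parameter triples to a single scalar set
#'
#' @param params A [risk_params()] object.
#' @param which `"central"`, `"min"` or `"max"`.
#' @return Named list of scalars, one per parameter.
#' @export
select_params <- function(params, which = c("central", "min", "max")) {
  which <- match.arg(which)
  stopifnot(inherits(params, "risk_params"))
  lapply(unclass(params), function(v) unname(v[[which]]))
}

# Paths to the packaged fixtures (in-package transcriptions of the printed
# population projection and risk-factor prevalence tables).
#' Packaged example data paths
#'
#' @param name One of `"population"`, `"prevalence"`, `"scenario1"`,
#'   `"scenario2"`.
#' @return File path inside the installed package.
#' @export
t2d_example <- function(name = c("population", "prevalence", "scenario1", "scenario2")) {
  name <- match.arg(name)
  file <- switch(name,
                 population = "population_brazil.csv",
                 prevalence = "prevalence_vigitel.csv",
                 scenario1 = "scenario1.yaml",
                 scenario2 = "scenario2.yaml")
  system.file("extdata", file, package = "t2dmarkov", mustWork = TRUE)
}

#' Load the packaged Brazilian population projection (millions)
#' @return An [age_sex_table()] with anchor years 2006, 2020, 2036.
#' @export
brazil_population <- function() {
  read_age_sex_table(t2d_example("population"), "population_millions")
}

#' Load the packaged risk-factor prevalence panel
#'
#' Self-reported diabetes, obesity (BMI > 30) and current smoking
#' prevalence by sex and age band for survey years 2006 and 2020, stored
#' as fractions.
#' @return An [age_sex_table()] with a `factor` column
#'   (`"t2d"`, `"obesity"`, `"smoking"`).
#' @export
brazil_prevalence <- function() {
  read_age_sex_table(t2d_example("prevalence"), "prevalence_fraction",
                     units = "percent")
}
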