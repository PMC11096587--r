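# Annual-cycle multistate cohort simulation. Six states per sex and age
# band: four alive pools (healthy, obese, smoker, diabetes) and two
# absorbing death states (diabetes-related, other). Each cycle applies
# diabetes incidence, mortality, risk-factor pool re-balancing toward the
# projected obesity/smoking paths, and demographic aging with new
# 25-year-old entrants taken from the population projection.

#' Model state labels
#' @export
STATES <- c("HEALTHY", "OBESE", "SMOKER", "DIABETES", "DEATH_T2D", "DEATH_OTHER")

ALIVE_STATES <- c("HEALTHY", "OBESE", "SMOKER", "DIABETES")

#' Simulation configuration
#'
#' @param start_year,end_year Simulation horizon (annual cycles).
#' @param calibration_year Year whose diabetes prevalence cross-section is
#'   used to back-calculate incidence and excess fatality; the resulting
#'   age/sex rates are held fixed over the horizon.
#' @param aging_fraction Fraction of each alive state moving up one age
#'   band per year (1/10 for ten-year bands under a uniform-age
#'   approximation).
#' @param mortality Optional named list (`M`, `W`) of all-cause mortality
#'   [age_profile()]s; defaults to the packaged synthetic Gompertz curves.
#' @param pooled_trends Fit risk-factor trends with a shared slope across
#'   bands (`TRUE`) or per-band slopes.
#' @return List with class `model_config`.
#' @export
model_config <- function(start_year = 2006, end_year = 2036,
                         calibration_year = 2010, aging_fraction = 0.1,
                         mortality = NULL, pooled_trends = TRUE) {
  if (start_year >= end_year) stop("model_config: start_year must precede end_year")
  if (aging_fraction < 0 || aging_fraction > 1) {
    stop("model_config: aging_fraction must lie in [0, 1]")
  }
  structure(list(start_year = as.integer(start_year),
                 end_year = as.integer(end_year),
                 calibration_year = as.integer(calibration_year),
                 aging_fraction = aging_fraction,
                 mortality = mortality,
                 pooled_trends = pooled_trends),
            class = "model_config")
}

as_scalar_params <- function(params, which = "central") {
  if (inherits(params, "risk_params")) select_params(params, which) else params
}

new_state_vector <- function(year) {
  structure(array(0, dim = c(length(SEXES), length(AGE_BANDS), length(STATES)),
                  dimnames = list(SEXES, AGE_BANDS, STATES)),
            class = "state_vector", year = as.integer(year))
}

#' Occupancy year of a state vector
#' @param state A `state_vector`.
#' @return Integer calendar year.
#' @export
state_year <- function(state) attr(state, "year")

#' Initialize state occupancies at the start year
#'
#' Per (sex, band), the alive population is split into the four pools by
#' [partition_states()] — with attributable fractions from [levin_par()]
#' using the incidence relative risks and current exposure prevalences —
#' and scaled by the band population. Death states start at zero. The
#' diabetes prevalence supplied here is expected to be already corrected
#' for self-report (see [apply_correction()]).
#'
#' @param pop Population slice data frame (columns `year,sex,age_band,value`,
#'   millions) at the start year.
#' @param prev Named list per sex of band-named prevalence vectors:
#'   `prev[[sex]]$t2d` (corrected), `$obesity`, `$smoking`.
#' @param params [risk_params()] or a scalar set from [select_params()].
#' @return A `state_vector` at the slice's year.
#' @export
initialize_states <- function(pop, prev, params) {
  ps <- as_scalar_params(params)
  year <- unique(pop$year)
  stopifnot(length(year) == 1L)
  st <- new_state_vector(year)
  for (s in SEXES) {
    popv <- stats::setNames(pop$value[pop$sex == s][match(AGE_BANDS, pop$age_band[pop$sex == s])],
                            AGE_BANDS)
    for (b in AGE_BANDS) {
      p_ob <- prev[[s]]$obesity[[b]]
      p_sm <- prev[[s]]$smoking[[b]]
      p_dm <- prev[[s]]$t2d[[b]]
      fr <- partition_states(p_ob, p_sm, p_dm,
                             levin_par(p_ob, ps$rr_inc_obesity),
                             levin_par(p_sm, ps$rr_inc_smoking))
      n <- popv[[b]]
      st[s, b, "HEALTHY"] <- fr$healthy * n
      st[s, b, "OBESE"] <- fr$obese * n
      st[s, b, "SMOKER"] <- fr$smoker * n
      st[s, b, "DIABETES"] <- fr$diabetes * n
    }
  }
  st
}

#' Advance the model one annual cycle
#'
#' Within-cycle event order, per (sex, band):
#' 1. *Incidence*: healthy leave at probability `1 - exp(-i)`, obese at
#'    `1 - exp(-i * rr_inc_obesity)`, smokers at
#'    `1 - exp(-i * rr_inc_smoking)`; entrants join the diabetes pool.
#' 2. *Mortality*: non-diabetic states die to `DEATH_OTHER` at
#'    `1 - exp(-m_other)`; the diabetes pool dies at
#'    `1 - exp(-(m_other + f))` with the excess share `f / (m_other + f)`
#'    booked to `DEATH_T2D`.
#' 3. *Re-balancing*: the alive non-diabetic population is re-partitioned
#'    so the obese/smoker pool shares track the projected factor paths for
#'    the next year (the diabetes pool is never re-balanced: no remission).
#' 4. *Aging*: `aging_fraction` of each alive state moves up one band; new
#'    25-year-old entrants top the youngest band up to the population
#'    projection, joining in its current pool proportions.
#'
#' @param state A `state_vector` at year y.
#' @param rates Named list per sex with band-named vectors `incidence`,
#'   `excess_fatality`, `mortality_other` (per-year hazards).
#' @param paths Named list per sex: `$obesity`, `$smoking` band-named
#'   target prevalences for year y+1.
#' @param params [risk_params()] or a scalar set.
#' @param config A [model_config()].
#' @param young_target Named vector (`M`, `W`): projected population of
#'   the youngest band at year y+1 (millions); entrants are added to reach
#'   it (never removed). Default `NULL` adds no entrants.
#' @return A `state_vector` at year y+1, with attribute `entrants`.
#' @export
step_cycle <- function(state, rates, paths, params, config,
                       young_target = NULL) {
  ps <- as_scalar_params(params)
  af <- config$aging_fraction
  y <- state_year(state)
  new <- state
  for (s in SEXES) {
    for (b in AGE_BANDS) {
      occ <- new[s, b, ]
      i <- rates[[s]]$incidence[[b]]
      f <- rates[[s]]$excess_fatality[[b]]
      m <- rates[[s]]$mortality_other[[b]]
      probs <- 1 - exp(-c(i, i * ps$rr_inc_obesity, i * ps$rr_inc_smoking, m, m + f))
      if (any(probs < 0 | probs > 1)) {
        stop("step_cycle: transition probability outside [0, 1] for sex ", s,
             " band ", b)
      }
      # 1. incidence
      inc <- c(HEALTHY = occ[["HEALTHY"]] * probs[1],
               OBESE = occ[["OBESE"]] * probs[2],
               SMOKER = occ[["SMOKER"]] * probs[3])
      occ[names(inc)] <- occ[names(inc)] - inc
      occ[["DIABETES"]] <- occ[["DIABETES"]] + sum(inc)
      # 2. mortality
      pm <- probs[4]
      d_nd <- occ[c("HEALTHY", "OBESE", "SMOKER")] * pm
      occ[c("HEALTHY", "OBESE", "SMOKER")] <- occ[c("HEALTHY", "OBESE", "SMOKER")] - d_nd
      d_dm <- occ[["DIABETES"]] * probs[5]
      occ[["DIABETES"]] <- occ[["DIABETES"]] - d_dm
      excess_share <- if (m + f > 0) f / (m + f) else 0
      occ[["DEATH_T2D"]] <- occ[["DEATH_T2D"]] + d_dm * excess_share
      occ[["DEATH_OTHER"]] <- occ[["DEATH_OTHER"]] + sum(d_nd) + d_dm * (1 - excess_share)
      # 3. risk-factor re-balancing toward next-year paths
      alive <- sum(occ[ALIVE_STATES])
      if (alive > 0) {
        p_dm <- occ[["DIABETES"]] / alive
        p_ob <- paths[[s]]$obesity[[b]]
        p_sm <- paths[[s]]$smoking[[b]]
        fr <- partition_states(p_ob, p_sm, min(p_dm, 1),
                               levin_par(p_ob, ps$rr_inc_obesity),
                               levin_par(p_sm, ps$rr_inc_smoking),
                               floor = TRUE)
        occ[["OBESE"]] <- fr$obese * alive
        occ[["SMOKER"]] <- fr$smoker * alive
        occ[["HEALTHY"]] <- fr$healthy * alive
      }
      new[s, b, ] <- occ
    }
  }
  # 4. aging across bands (alive states only; death states are cumulative)
  entrants <- stats::setNames(numeric(length(SEXES)), SEXES)
  if (af > 0 || !is.null(young_target)) {
    for (s in SEXES) {
      cur <- new[s, , ALIVE_STATES, drop = TRUE]
      aged <- cur * (1 - af)
      aged[length(AGE_BANDS), ] <- aged[length(AGE_BANDS), ] + af * cur[length(AGE_BANDS), ]
      aged[-1, ] <- aged[-1, , drop = FALSE] + af * cur[-length(AGE_BANDS), , drop = FALSE]
      if (!is.null(young_target)) {
        have <- sum(aged[1, ])
        add <- max(young_target[[s]] - have, 0)
        shares <- if (have > 0) aged[1, ] / have else c(1, 0, 0, 0)
        aged[1, ] <- aged[1, ] + add * shares
        entrants[[s]] <- add
      }
      new[s, , ALIVE_STATES] <- aged
    }
  }
  attr(new, "year") <- y + 1L
  attr(new, "entrants") <- entrants
  new
}

summarize_state <- function(state) {
  out <- data.frame(year = state_year(state), sex = c(SEXES, "TOTAL"),
                    prevalence = NA_real_, cases_millions = NA_real_,
                    alive_millions = NA_real_)
  alive <- prev <- cases <- stats::setNames(numeric(2), SEXES)
  for (s in SEXES) {
    alive[s] <- sum(state[s, , ALIVE_STATES])
    cases[s] <- sum(state[s, , "DIABETES"])
    prev[s] <- if (alive[s] > 0) cases[s] / alive[s] else 0
  }
  out$prevalence <- c(prev, weighted_total_prevalence(prev["M"], prev["W"],
                                                      alive["M"], alive["W"]))
  out$cases_millions <- c(cases, sum(cases))
  out$alive_millions <- c(alive, sum(alive))
  out
}

#' Run the full multistate forecast
#'
#' Orchestrates one complete model run: fits risk-factor trends, projects
#' factor paths (optionally under a policy scenario), back-calculates
#' transition rates from the calibration-year diabetes cross-section,
#' initializes the start-year states and iterates annual cycles to the
#' horizon.
#'
#' @param pop Population [age_sex_table()] (millions) with anchor years
#'   covering the horizon.
#' @param prev Observed prevalence [age_sex_table()] with factor column
#'   (`"t2d"`, `"obesity"`, `"smoking"`); diabetes values are raw
#'   self-report and are corrected internally.
#' @param params A [risk_params()] object.
#' @param config A [model_config()].
#' @param scenario Optional [scenario_spec()] modifying the obesity path.
#' @param param_set Which value of each parameter triple to use:
#'   `"central"`, `"min"` or `"max"`.
#' @return A `forecast_result` data frame (`year`, `sex` including
#'   `"TOTAL"`, `prevalence`, `cases_millions`, `alive_millions`) with the
#'   state trajectory, rates and trends in attributes.
#' @export
run_markov <- function(pop, prev, params = risk_params(),
                       config = model_config(), scenario = NULL,
                       param_set = "central") {
  ps <- as_scalar_params(params, param_set)
  years <- config$start_year:config$end_year
  paths <- build_factor_paths(prev, years, scenario,
                              pooled = config$pooled_trends)
  mortality <- config$mortality %||%
    list(M = default_mortality_profile("M"), W = default_mortality_profile("W"))
  # calibration: back-calculate incidence / excess fatality once
  calib <- interpolate_years(prev, config$calibration_year, factor = "t2d")
  rates <- list()
  for (s in SEXES) {
    raw <- stats::setNames(calib$value[calib$sex == s][match(AGE_BANDS, calib$age_band[calib$sex == s])],
                           AGE_BANDS)
    corrected <- apply_correction(raw, ps$correction_factor)
    rates[[s]] <- estimate_transition_rates(corrected, mortality[[s]],
                                            ps$rr_mort_t2d)
  }
  # initial states from the start-year cross-section
  pop0 <- interpolate_population(pop, config$start_year)
  prev0 <- list()
  for (s in SEXES) {
    prev0[[s]] <- list(
      t2d = apply_correction(ast_slice(prev, config$start_year, s, "t2d"),
                             ps$correction_factor),
      obesity = ast_slice(prev, config$start_year, s, "obesity"),
      smoking = ast_slice(prev, config$start_year, s, "smoking"))
  }
  state <- initialize_states(pop0, prev0, ps)
  states <- list(state)
  cum_entrants <- stats::setNames(numeric(2), SEXES)
  for (y in years[-length(years)]) {
    yn <- as.character(y + 1)
    step_paths <- lapply(stats::setNames(SEXES, SEXES), function(s) {
      list(obesity = paths[[s]]$obesity[, yn],
           smoking = paths[[s]]$smoking[, yn])
    })
    popn <- interpolate_population(pop, y + 1)
    young <- stats::setNames(
      popn$value[popn$age_band == AGE_BANDS[1]][match(SEXES, popn$sex[popn$age_band == AGE_BANDS[1]])],
      SEXES)
    state <- step_cycle(state, rates, step_paths, ps, config,
                        young_target = young)
    cum_entrants <- cum_entrants + attr(state, "entrants")
    states[[length(states) + 1L]] <- state
  }
  out <- do.call(rbind, lapply(states, summarize_state))
  rownames(out) <- NULL
  structure(out,
            class = c("forecast_result", "data.frame"),
            states = states, rates = rates,
            trends = attr(paths, "trends"),
            config = config, param_set = param_set,
            scenario = if (!is.null(scenario)) scenario$name else "baseline",
            cum_entrants = cum_entrants)
}

#' Extreme-value sensitivity bounds
#'
#' Re-runs the model with every parameter at its joint minimum and joint
#' maximum (the conservative extreme-scenario approach) and reports, per
#' cell, the envelope of the three runs: the bounds are taken after
#' evaluation, not assumed monotone in the parameters, so they always
#' bracket the central value.
#'
#' @param run_fn Function of one argument (`"min"`, `"central"`, `"max"`)
#'   returning a `forecast_result`; typically a closure over
#'   [run_markov()].
#' @return A `forecast_bounds` data frame: `year`, `sex`, `metric`
#'   (`"prevalence"`, `"cases_millions"`), `central`, `min`, `max`.
#' @export
extreme_bounds <- function(run_fn) {
  runs <- lapply(stats::setNames(c("min", "central", "max"),
                                 c("min", "central", "max")), run_fn)
  long <- function(r, tag) {
    rbind(data.frame(year = r$year, sex = r$sex, metric = "prevalence",
                     value = r$prevalence),
          data.frame(year = r$year, sex = r$sex, metric = "cases_millions",
                     value = r$cases_millions))
  }
  key <- function(df) paste(df$year, df$sex, df$metric)
  ctr <- long(runs$central)
  lo <- long(runs$min); hi <- long(runs$max)
  stopifnot(identical(key(ctr), key(lo)), identical(key(ctr), key(hi)))
  out <- data.frame(year = ctr$year, sex = ctr$sex, metric = ctr$metric,
                    central = ctr$value,
                    min = pmin(ctr$value, lo$value, hi$value),
                    max = pmax(ctr$value, lo$value, hi$value))
  structure(out, class = c("forecast_bounds", "data.frame"))
}

result_cell <- function(result, year, sex, metric = "prevalence") {
  v <- result[[metric]][result$year == year & result$sex == sex]
  if (length(v) != 1L) stop("no cell for year ", year, " sex ", sex)
  v
}

#' Cases prevented by a scenario at a horizon year
#'
#' Per sex, `(prevalence_baseline - prevalence_scenario) * population`
#' using the projected population at the horizon; total is the sum over
#' sexes.
#'
#' @param baseline,scenario `forecast_result`s covering `year`.
#' @param pop Population [age_sex_table()] (millions).
#' @param year Horizon year.
#' @return Named vector (`M`, `W`, `TOTAL`) of prevented cases, millions.
#' @export
prevented_cases <- function(baseline, scenario, pop, year) {
  if (!(year %in% baseline$year) || !(year %in% scenario$year)) {
    stop("prevented_cases: both runs must cover year ", year)
  }
  slice <- interpolate_population(pop, year)
  out <- stats::setNames(numeric(3), c(SEXES, "TOTAL"))
  for (s in SEXES) {
    dp <- result_cell(baseline, year, s) - result_cell(scenario, year, s)
    out[s] <- dp * sum(slice$value[slice$sex == s])
  }
  out["TOTAL"] <- sum(out[SEXES])
  out
}

#' Compare the model against an observed prevalence series
#'
#' For every overlapping year, the observed self-reported diabetes
#' prevalence (population-weighted over sex and band, multiplied by the
#' correction factor) is set against the modelled total prevalence.
#'
#' @param result A `forecast_result`.
#' @param observed Observed prevalence [age_sex_table()] with a `"t2d"`
#'   factor (raw self-report fractions).
#' @param pop Population [age_sex_table()] for weighting.
#' @param factor Correction multiplier applied to the observed series.
#' @return Data frame `year`, `observed_corrected`, `modelled`,
#'   `abs_diff`, `rel_diff`, with the mean absolute error in attribute
#'   `mae`.
#' @export
validate_series <- function(result, observed, pop, factor = 1.5) {
  yrs <- intersect(ast_years(observed), unique(result$year))
  if (length(yrs) == 0L) stop("validate_series: no overlapping years")
  rows <- lapply(yrs, function(y) {
    slice <- interpolate_population(pop, y)
    num <- den <- 0
    for (s in SEXES) {
      pv <- ast_slice(observed, y, s, "t2d")
      pw <- stats::setNames(slice$value[slice$sex == s][match(AGE_BANDS, slice$age_band[slice$sex == s])],
                            AGE_BANDS)
      num <- num + sum(pv * pw)
      den <- den + sum(pw)
    }
    obs <- apply_correction(num / den, factor)
    mod <- result_cell(result, y, "TOTAL")
    data.frame(year = y, observed_corrected = obs, modelled = mod,
               abs_diff = abs(mod - obs),
               rel_diff = abs(mod - obs) / obs)
  })
  out <- do.call(rbind, rows)
  attr(out, "mae") <- mean(out$abs_diff)
  out
}

#' Write a bounds table as tidy CSV
#'
#' Columns `year,sex,metric,central,min,max`.
#'
#' @param bounds A `forecast_bounds` (or `forecast_result`, written
#'   without bounds columns).
#' @param path Output path.
#' @export
write_forecast_csv <- function(bounds, path) {
  utils::write.csv(as.data.frame(bounds), path, row.names = FALSE)
  invisible(path)
}
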