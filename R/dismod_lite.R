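# Illness-death model on a 1-year age grid: forward cohort simulation
# (the verification oracle) and back-calculation of diabetes incidence and
# excess case fatality from cross-sectional prevalence, all-cause mortality
# and the mortality relative risk, with remission fixed at zero.

#' Default 1-year age grid
#' @return Integer ages 25..100.
#' @export
default_age_grid <- function() 25:100

#' Construct an age profile
#'
#' One number per age-grid point: a prevalence fraction or a per-year
#' hazard.
#'
#' @param ages Strictly increasing ages in years (within 25-100).
#' @param values Numeric values, one per age; hazards must be >= 0,
#'   prevalences in \[0, 1\].
#' @param type `"hazard"` or `"prevalence"`.
#' @return List with class `age_profile` (`ages`, `values`, `type`).
#' @export
age_profile <- function(ages, values, type = c("hazard", "prevalence")) {
  type <- match.arg(type)
  if (length(ages) != length(values)) {
    stop("age_profile: ages and values must have equal length")
  }
  if (any(diff(ages) <= 0)) stop("age_profile: ages must be strictly increasing")
  if (type == "hazard" && any(values < 0)) {
    stop("age_profile: hazards must be >= 0")
  }
  if (type == "prevalence" && any(values < 0 | values > 1)) {
    stop("age_profile: prevalences must lie in [0, 1]")
  }
  structure(list(ages = as.numeric(ages), values = as.numeric(values),
                 type = type), class = "age_profile")
}

check_shared_grid <- function(...) {
  profs <- list(...)
  ages <- profs[[1]]$ages
  for (p in profs[-1]) {
    if (!isTRUE(all.equal(p$ages, ages))) {
      stop("age profiles must share one grid")
    }
  }
  ages
}

#' Split all-cause mortality into healthy and diseased hazards
#'
#' Given the all-cause hazard `m_all`, disease prevalence `p` and the usual
#' mortality relative risk `rr` (diseased vs healthy), returns
#' `m_healthy = m_all / (1 + p (rr - 1))` and `m_diseased = rr * m_healthy`,
#' so that `p * m_diseased + (1 - p) * m_healthy = m_all` exactly.
#'
#' @param m_all All-cause mortality hazard (per year, >= 0).
#' @param p Disease prevalence fraction.
#' @param rr Usual mortality relative risk (> 0).
#' @return List `m_healthy`, `m_diseased`. Vectorized.
#' @export
split_mortality <- function(m_all, p, rr) {
  if (any(m_all < 0)) stop("split_mortality: m_all must be >= 0")
  if (any(p < 0 | p > 1)) stop("split_mortality: p must lie in [0, 1]")
  if (any(rr <= 0)) stop("split_mortality: rr must be > 0")
  m_healthy <- m_all / (1 + p * (rr - 1))
  list(m_healthy = m_healthy, m_diseased = rr * m_healthy)
}

#' Forward-simulate an illness-death cohort
#'
#' Integrates the susceptible/case system
#' `dS/da = -(i + m_h) S`, `dC/da = i S - (m_h + f) C` from `S = 1, C = 0`
#' at `start_age` with a fixed-step fourth-order Runge-Kutta scheme at the
#' grid resolution, and returns the prevalence profile
#' `p(a) = C / (S + C)`. With zero remission this is the exact forward
#' counterpart of [back_calculate_incidence()] and serves as its
#' verification oracle.
#'
#' @param incidence Incidence hazard [age_profile()].
#' @param m_healthy Mortality hazard of the non-diseased [age_profile()].
#' @param excess_fatality Excess mortality hazard of the diseased
#'   [age_profile()].
#' @param start_age Age at which the cohort is disease-free (defaults to
#'   the first grid age).
#' @return Prevalence [age_profile()] on the shared grid (zero below
#'   `start_age`).
#' @export
forward_simulate <- function(incidence, m_healthy, excess_fatality,
                             start_age = NULL) {
  ages <- check_shared_grid(incidence, m_healthy, excess_fatality)
  if (is.null(start_age)) start_age <- ages[1]
  if (!start_age %in% ages) stop("forward_simulate: start_age not on the grid")
  i_fun <- stats::approxfun(ages, incidence$values, rule = 2)
  mh_fun <- stats::approxfun(ages, m_healthy$values, rule = 2)
  f_fun <- stats::approxfun(ages, excess_fatality$values, rule = 2)
  deriv <- function(a, y, parms) {
    list(c(S = -(i_fun(a) + mh_fun(a)) * y[1],
           C = i_fun(a) * y[1] - (mh_fun(a) + f_fun(a)) * y[2]))
  }
  sim_ages <- ages[ages >= start_age]
  sol <- deSolve::rk4(y = c(S = 1, C = 0), times = sim_ages,
                      func = deriv, parms = NULL)
  S <- sol[, "S"]; C <- sol[, "C"]
  alive <- S + C
  if (any(alive <= .Machine$double.xmin)) {
    stop("forward_simulate: cohort extinct within the age range")
  }
  prev <- numeric(length(ages))
  prev[ages >= start_age] <- C / alive
  age_profile(ages, pmin(pmax(prev, 0), 1), "prevalence")
}

#' Back-calculate incidence and excess fatality from prevalence
#'
#' Inverts the illness-death model: at each grid age, all-cause mortality
#' is split into healthy and diseased hazards via [split_mortality()], the
#' excess fatality is `f = m_diseased - m_healthy`, and incidence is
#' recovered from the prevalence gradient as
#' `i(a) = p'(a) / (1 - p) + p * f`, using central differences (one-sided
#' at the grid ends) and flooring at zero. Remission must be zero.
#'
#' @param prevalence Prevalence [age_profile()].
#' @param m_all All-cause mortality hazard [age_profile()] on the same grid.
#' @param rr Usual mortality relative risk, diseased vs healthy.
#' @param remission Remission hazard; only 0 is supported.
#' @return List of two [age_profile()]s: `incidence` and `excess_fatality`.
#' @export
back_calculate_incidence <- function(prevalence, m_all, rr, remission = 0) {
  if (remission != 0) {
    stop("back_calculate_incidence: only remission = 0 is supported")
  }
  ages <- check_shared_grid(prevalence, m_all)
  p <- prevalence$values
  if (any(p >= 1)) {
    stop("back_calculate_incidence: prevalence reaches 1 (degenerate)")
  }
  sm <- split_mortality(m_all$values, p, rr)
  f <- sm$m_diseased - sm$m_healthy
  dp <- grid_gradient(ages, p)
  i_raw <- dp / (1 - p) + p * f
  if (any(i_raw < -1e-6)) {
    warning("back_calculate_incidence: negative incidence at age(s) ",
            paste(ages[i_raw < -1e-6], collapse = ", "), "; floored at 0")
  }
  list(incidence = age_profile(ages, pmax(i_raw, 0), "hazard"),
       excess_fatality = age_profile(ages, pmax(f, 0), "hazard"))
}

# Central differences on a (possibly non-uniform) grid, one-sided at ends.
grid_gradient <- function(x, y) {
  n <- length(x)
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (x[2] - x[1])
  g[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) {
    g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  }
  g
}

#' Expand band-level values to the 1-year age grid
#'
#' Piecewise-linear interpolation through the band midpoints (the open 75+
#' band is represented by age 82), held constant beyond the outermost
#' midpoints.
#'
#' @param values_by_band Numeric vector named by the six band labels.
#' @param grid Age grid (default [default_age_grid()]).
#' @param type Profile type for the result.
#' @return An [age_profile()].
#' @export
bands_to_profile <- function(values_by_band, grid = default_age_grid(),
                             type = c("prevalence", "hazard")) {
  type <- match.arg(type)
  v <- values_by_band[AGE_BANDS]
  if (any(is.na(v))) stop("bands_to_profile: values for all six bands required")
  out <- stats::approx(band_midpoints, v, xout = grid, rule = 2)$y
  age_profile(grid, out, type)
}

#' Aggregate an age profile back to band-level values
#'
#' Weighted mean per band. Default weights follow the survival curve
#' implied by a mortality profile (so the oldest ages of the open band do
#' not dominate); uniform weights if no mortality is given.
#'
#' @param profile An [age_profile()].
#' @param mortality Optional all-cause mortality [age_profile()] on the
#'   same grid, used to build survival weights.
#' @return Numeric vector named by band.
#' @export
profile_to_bands <- function(profile, mortality = NULL) {
  ages <- profile$ages
  w <- rep(1, length(ages))
  if (!is.null(mortality)) {
    check_shared_grid(profile, mortality)
    h <- mortality$values
    w <- exp(-c(0, cumsum((h[-length(h)] + h[-1]) / 2 * diff(ages))))
  }
  out <- stats::setNames(numeric(length(AGE_BANDS)), AGE_BANDS)
  for (b in seq_along(AGE_BANDS)) {
    sel <- ages >= band_lower[b] & ages <= band_upper[b]
    out[b] <- sum(profile$values[sel] * w[sel]) / sum(w[sel])
  }
  out
}

#' Synthetic all-cause mortality profile (Gompertz)
#'
#' A packaged default all-cause mortality hazard by age and sex. This is a
#' synthetic Gompertz curve, `m(a) = m0 * exp(b * (a - 25))`, with
#' sex-specific level and slope chosen to give plausible adult hazards for
#' a middle-income country (men ~0.0015/yr at 25 rising to ~0.08/yr at 80;
#' women lower). It is *not* an official life table; users with real
#' life-table data should supply it via [read_life_table()].
#'
#' @param sex `"M"` or `"W"`.
#' @param grid Age grid.
#' @return Hazard [age_profile()].
#' @export
default_mortality_profile <- function(sex = c("M", "W"),
                                      grid = default_age_grid()) {
  sex <- match.arg(sex)
  pars <- switch(sex,
                 M = c(m0 = 0.0015, b = 0.072),
                 W = c(m0 = 0.0008, b = 0.078))
  age_profile(grid, pars["m0"] * exp(pars["b"] * (grid - 25)), "hazard")
}

#' Read a life table CSV into per-sex mortality profiles
#'
#' Expected columns: `sex,age,mortality_rate` with per-year hazards.
#' Hazards are interpolated onto the model's age grid.
#'
#' @param path CSV file path.
#' @param grid Age grid.
#' @return Named list of hazard [age_profile()]s, one per sex.
#' @export
read_life_table <- function(path, grid = default_age_grid()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sex", "age", "mortality_rate")
  if (!all(needed %in% names(df))) {
    stop("read_life_table: columns sex, age, mortality_rate required")
  }
  out <- list()
  for (s in SEXES) {
    sub <- df[df$sex == s, , drop = FALSE]
    if (nrow(sub) < 2L) stop("read_life_table: need >= 2 ages for sex ", s)
    sub <- sub[order(sub$age), ]
    v <- stats::approx(sub$age, sub$mortality_rate, xout = grid, rule = 2)$y
    out[[s]] <- age_profile(grid, pmax(v, 0), "hazard")
  }
  out
}

#' Estimate band-level transition rates from a prevalence cross-section
#'
#' The calibration step standing in for the external incidence estimation:
#' band-level (corrected) diabetes prevalence is expanded to the 1-year
#' grid, incidence and excess fatality are back-calculated against the
#' all-cause mortality profile, and all three hazards are aggregated back
#' to bands with survival weights. `mortality_other` is the healthy-group
#' hazard from [split_mortality()].
#'
#' @param prev_by_band Corrected diabetes prevalence fractions, named by
#'   band.
#' @param mortality All-cause mortality hazard [age_profile()] for the sex.
#' @param rr_mort Usual mortality relative risk, diseased vs healthy.
#' @param grid Age grid.
#' @return List of band-named vectors: `incidence`, `excess_fatality`,
#'   `mortality_other`.
#' @export
estimate_transition_rates <- function(prev_by_band, mortality,
                                      rr_mort, grid = default_age_grid()) {
  prev_prof <- bands_to_profile(prev_by_band, grid, "prevalence")
  bc <- back_calculate_incidence(prev_prof, mortality, rr_mort)
  mh <- split_mortality(mortality$values, prev_prof$values, rr_mort)$m_healthy
  mh_prof <- age_profile(grid, mh, "hazard")
  list(incidence = profile_to_bands(bc$incidence, mortality),
       excess_fatality = profile_to_bands(bc$excess_fatality, mortality),
       mortality_other = profile_to_bands(mh_prof, mortality))
}
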