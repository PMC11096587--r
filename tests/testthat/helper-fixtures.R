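# Shared fixtures: packaged tables are read once per test run.
fix_pop <- brazil_population()
fix_prev <- brazil_prevalence()

# Band-named vector of equal values
flat_bands <- function(x) stats::setNames(rep(x, length(AGE_BANDS)), AGE_BANDS)

# A small exact-linear prevalence panel: p(band, year) = a_band + slope * t
linear_panel <- function(intercepts, slope, years = 2006:2012, sex = "M",
                         factor = NULL) {
  grid <- expand.grid(year = years, age_band = AGE_BANDS,
                      stringsAsFactors = FALSE)
  grid$sex <- sex
  grid$value <- intercepts[grid$age_band] + slope * (grid$year - min(years))
  if (!is.null(factor)) grid$factor <- factor
  age_sex_table(grid, "prevalence_fraction")
}
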