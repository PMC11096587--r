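test_that("packaged fixtures transcribe the printed tables", {
  expect_equal(unname(ast_slice(fix_pop, 2006, "M")["25-34"]), 15.6)
  expect_equal(unname(ast_slice(fix_pop, 2036, "W")["75+"]), 9.7)
  expect_equal(unname(ast_slice(fix_prev, 2020, "W", "obesity")["75+"]), 0.208)
  expect_equal(unname(ast_slice(fix_prev, 2006, "M", "smoking")["45-54"]), 0.226)
  # totals are recomputed as column sums, never read from a totals row
  expect_equal(sum(ast_slice(fix_pop, 2020, "M")), 64.6)
  # the printed totals row (48.8 + 51.9) disagrees with its own column
  # sums; totals are always recomputed from the per-band values
  expect_equal(sum(ast_slice(fix_pop, 2006, "M")) + sum(ast_slice(fix_pop, 2006, "W")),
               100.2)
})

test_that("reader validates structure and ranges", {
  empty <- tempfile(fileext = ".csv")
  writeLines("year,sex,age_band,value", empty)
  expect_error(read_age_sex_table(empty, "population_millions"), "empty")

  gap <- tempfile(fileext = ".csv")
  df <- as.data.frame(fix_pop)
  df <- df[!(df$year == 2006 & df$sex == "M" & df$age_band == "45-54"), ]
  utils::write.csv(df, gap, row.names = FALSE)
  expect_error(read_age_sex_table(gap, "population_millions"), "45-54")

  bad <- tempfile(fileext = ".csv")
  writeLines(c("year,sex,age_band,value",
               paste(2006, "M", AGE_BANDS, c(120, 5, 5, 5, 5, 5), sep = ","),
               paste(2006, "W", AGE_BANDS, 5, sep = ",")), bad)
  expect_error(read_age_sex_table(bad, "prevalence_fraction", units = "percent"),
               "\\[0, 100\\]")
})

test_that("write/read round-trip is the identity on values", {
  path <- tempfile(fileext = ".csv")
  write_age_sex_table(fix_pop, path)
  back <- read_age_sex_table(path, "population_millions")
  expect_equal(back$value, fix_pop$value, tolerance = 1e-12)
  expect_equal(back$age_band, fix_pop$age_band)
})

test_that("population interpolation is exact at anchors and linear between", {
  at_anchor <- interpolate_population(fix_pop, 2020)
  expect_equal(at_anchor$value[at_anchor$sex == "M" & at_anchor$age_band == "25-34"],
               17.6)
  mid <- interpolate_population(fix_pop, 2013)
  expect_equal(mid$value[mid$sex == "M" & mid$age_band == "25-34"],
               15.6 + (17.6 - 15.6) * 7 / 14)  # 16.6
  late <- interpolate_population(fix_pop, 2028)
  expect_equal(late$value[late$sex == "W" & late$age_band == "75+"],
               4.8 + (9.7 - 4.8) * 8 / 16)  # 7.25
  expect_error(interpolate_population(fix_pop, 2040), "outside")
  # monotone in year when anchors order the same way (M 55-64 rises throughout)
  vals <- vapply(2006:2036, function(y) {
    sl <- interpolate_population(fix_pop, y)
    sl$value[sl$sex == "M" & sl$age_band == "55-64"]
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("weighted total prevalence is the population-weighted mean", {
  expect_equal(weighted_total_prevalence(0.110, 0.106, 48.8, 51.9),
               (0.110 * 48.8 + 0.106 * 51.9) / (48.8 + 51.9))
  expect_equal(round(weighted_total_prevalence(0.110, 0.106, 48.8, 51.9), 3),
               0.108)
  expect_equal(weighted_total_prevalence(0.3, 0.3, 7, 13), 0.3)
  expect_equal(weighted_total_prevalence(0.2, 0.0, 10, 30), 0.05)
  expect_error(weighted_total_prevalence(0.1, 0.1, 0, 0), "> 0")
  # lies between its inputs for random valid inputs
  set.seed(42)
  for (k in 1:200) {
    pm <- runif(1); pw <- runif(1); nm <- runif(1, 1, 100); nw <- runif(1, 1, 100)
    w <- weighted_total_prevalence(pm, pw, nm, nw)
    expect_gte(w, min(pm, pw))
    expect_lte(w, max(pm, pw))
  }
})

test_that("risk parameter triples are validated", {
  p <- risk_params()
  expect_s3_class(p, "risk_params")
  expect_identical(unname(p$remission_rate), c(0, 0, 0))
  expect_equal(unname(p$correction_factor["central"]), 1.5)
  expect_error(risk_params(rr_inc_obesity = c(3, 2, 4)), "min <= central")
  expect_error(risk_params(remission_rate = c(0, 0.1, 0.2)), "remission")
  sel <- select_params(p, "max")
  expect_equal(sel$rr_inc_obesity, 4)
  expect_equal(sel$remission_rate, 0)
})
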