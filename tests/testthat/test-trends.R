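test_that("pooled OLS recovers an exact linear panel", {
  a <- stats::setNames(seq(0.10, 0.35, 0.05), AGE_BANDS)
  panel <- linear_panel(a, slope = 0.005)
  tr <- fit_pooled_trend(panel, sex = "M")
  expect_equal(unname(tr$slope), rep(0.005, 6), tolerance = 1e-12)
  expect_equal(tr$intercepts, a, tolerance = 1e-12)
  expect_equal(unname(stats::residuals(tr$fit)), rep(0, nrow(panel)),
               tolerance = 1e-12)
  # projection reproduces in-window values exactly
  expect_equal(as.numeric(project_trend(tr, 2010, "45-54")),
               a[["45-54"]] + 0.005 * 4)
})

test_that("noise orthogonal to the time regressor leaves the slope unchanged", {
  a <- stats::setNames(rep(0.2, 6), AGE_BANDS)
  panel <- linear_panel(a, slope = 0.004, years = 2006:2010)
  # perturbation even in centred time (+eps at both end years, same in every
  # band): orthogonal to the slope regressor, so OLS absorbs it in the
  # intercepts and the slope is untouched
  t <- panel$year - mean(unique(panel$year))
  eps <- 0.01
  panel$value <- panel$value + eps * (abs(t) == max(abs(t)))
  tr <- fit_pooled_trend(panel, sex = "M")
  expect_equal(unname(tr$slope[1]), 0.004, tolerance = 1e-10)
})

test_that("fit requires two distinct years", {
  a <- stats::setNames(rep(0.2, 6), AGE_BANDS)
  one_year <- linear_panel(a, 0, years = 2006)
  expect_error(fit_pooled_trend(one_year, sex = "M"), "distinct years")
})

test_that("projection clamps to [0, 1] and flags the clamp", {
  a <- stats::setNames(rep(0.05, 6), AGE_BANDS)
  panel <- linear_panel(a, slope = -0.01, years = 2020:2022)
  tr <- fit_pooled_trend(panel, sex = "M")
  # 0.05 - 0.01 * (year - 2020) crosses zero at 2025; clamped from 2026 on
  expect_equal(as.numeric(project_trend(tr, 2025, "25-34")), 0)
  at_2030 <- project_trend(tr, 2030)
  expect_equal(as.numeric(at_2030), rep(0, 6))
  expect_length(attr(at_2030, "clamped"), 6)
  expect_error(project_trend(tr, 2019), "precedes")
  expect_error(project_trend(tr, 2025, "80+"), "unknown band")
  flat <- fit_pooled_trend(linear_panel(a, 0, years = 2020:2022), sex = "M")
  expect_equal(as.numeric(project_trend(flat, 2036)), rep(0.05, 6))
})

test_that("scenario paths compound from the start-year value", {
  years <- 2015:2036
  base <- stats::setNames(0.20 + 0.002 * (years - 2015), years)
  s0 <- scenario_spec("null", 0, "relative")
  expect_equal(apply_scenario(base, s0)[as.character(2015:2019)],
               base[as.character(2015:2019)])
  s1 <- scenario_spec("one_pct", -0.01, "relative")
  s2 <- scenario_spec("five_pct", -0.05, "relative")
  p1 <- apply_scenario(base, s1)
  p2 <- apply_scenario(base, s2)
  v0 <- base[["2020"]]
  expect_equal(unname(p1[["2036"]]), v0 * 0.99^16)  # multiplier 0.8515
  expect_equal(unname(p2[["2036"]]), v0 * 0.95^16)  # multiplier 0.4401
  # pointwise dominance for negative change on a non-decreasing baseline
  post <- as.character(2020:2036)
  expect_true(all(p2[post] <= p1[post]))
  expect_true(all(p1[post] <= base[post]))
  # absolute mode floors at zero
  sa <- scenario_spec("abs", -0.02, "absolute_pp")
  pa <- apply_scenario(base, sa)
  expect_equal(unname(pa[["2036"]]), max(v0 - 0.02 * 16, 0))
})

test_that("packaged scenario files parse to the documented settings", {
  s1 <- read_scenario(t2d_example("scenario1"))
  expect_equal(s1$annual_change, -0.01)
  expect_equal(s1$mode, "relative")
  expect_equal(c(s1$start_year, s1$end_year), c(2020L, 2036L))
  s2 <- read_scenario(t2d_example("scenario2"))
  expect_equal(s2$annual_change, -0.05)
  expect_error(scenario_spec("bad", -1.5, "relative"), "exceed -1")
  expect_error(scenario_spec("bad", 0, start_year = 2036, end_year = 2020),
               "precede")
})

test_that("slope is recovered within 3 SE on self-simulated panels", {
  a <- stats::setNames(seq(0.15, 0.30, 0.03), AGE_BANDS)
  true_slope <- 0.004
  hits <- 0
  n_rep <- 40
  set.seed(31)
  for (k in seq_len(n_rep)) {
    panel <- linear_panel(a, true_slope, years = 2006:2020)
    panel$value <- panel$value + stats::rnorm(nrow(panel), 0, 0.01)
    panel$value <- pmin(pmax(panel$value, 0), 1)
    tr <- fit_pooled_trend(panel, sex = "M")
    se <- summary(tr$fit)$coefficients["t", "Std. Error"]
    if (abs(tr$slope[1] - true_slope) <= 3 * se) hits <- hits + 1
  }
  expect_gte(hits, round(0.9 * n_rep))
})
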