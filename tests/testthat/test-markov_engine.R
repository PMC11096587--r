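# Helpers to build minimal states, rates and paths for single-step checks.
make_pop_df <- function(value, year = 2006) {
  df <- expand.grid(year = year, sex = SEXES, age_band = AGE_BANDS,
                    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  df$value <- value
  df
}

make_prev_list <- function(t2d = 0, obesity = 0, smoking = 0) {
  one <- list(t2d = flat_bands(t2d), obesity = flat_bands(obesity),
              smoking = flat_bands(smoking))
  list(M = one, W = one)
}

make_rates <- function(i = 0, f = 0, m = 0) {
  one <- list(incidence = flat_bands(i), excess_fatality = flat_bands(f),
              mortality_other = flat_bands(m))
  list(M = one, W = one)
}

make_paths <- function(obesity = 0, smoking = 0) {
  one <- list(obesity = flat_bands(obesity), smoking = flat_bands(smoking))
  list(M = one, W = one)
}

central <- select_params(risk_params(), "central")

test_that("initialization scales the pool partition by population", {
  st0 <- initialize_states(make_pop_df(1), make_prev_list(), central)
  expect_equal(sum(st0["M", , "HEALTHY"]), 6)  # everyone healthy
  expect_equal(sum(st0[, , c("OBESE", "SMOKER", "DIABETES", "DEATH_T2D",
                             "DEATH_OTHER")]), 0)

  # worked partition (0.2 obese, 0.1 smoker, 0.1 diabetes, PAR 0.3 / 0.1)
  # on a 1.0-million band: 0.66 / 0.17 / 0.07 / 0.10 million
  prev <- make_prev_list(t2d = 0.1, obesity = 0.2, smoking = 0.1)
  ps <- central
  ps$rr_inc_obesity <- 1 + 0.3 / (0.2 * (1 - 0.3))   # makes PAR(0.2, rr) = 0.3
  ps$rr_inc_smoking <- 1 + 0.1 / (0.1 * (1 - 0.1))   # makes PAR(0.1, rr) = 0.1
  st <- initialize_states(make_pop_df(1), prev, ps)
  expect_equal(unname(st["M", "35-44", ]),
               c(0.66, 0.17, 0.07, 0.10, 0, 0), tolerance = 1e-12)
})

test_that("a null cycle is the identity", {
  prev <- make_prev_list(t2d = 0.1, obesity = 0.2, smoking = 0.1)
  st <- initialize_states(make_pop_df(1), prev, central)
  cfg <- model_config(aging_fraction = 0)
  # paths matching the current exposure prevalences reproduce the same pools
  nxt <- step_cycle(st, make_rates(), make_paths(obesity = 0.2, smoking = 0.1),
                    central, cfg)
  expect_equal(unclass(nxt), unclass(st), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(state_year(nxt), state_year(st) + 1L)
})

test_that("incidence and mortality flows match hazard arithmetic", {
  cfg <- model_config(aging_fraction = 0)
  # 1000 healthy, i = 0.1, no mortality: 1000 (1 - e^-0.1) = 95.16 new cases
  st <- initialize_states(make_pop_df(1000), make_prev_list(), central)
  nxt <- step_cycle(st, make_rates(i = 0.1), make_paths(), central, cfg)
  expect_equal(unname(nxt["M", "25-34", "DIABETES"]), 1000 * (1 - exp(-0.1)),
               tolerance = 1e-9)

  # 100 diabetics, m = 0.01, f = 0.01: 1.980 deaths, split equally
  st2 <- initialize_states(make_pop_df(100), make_prev_list(t2d = 1), central)
  expect_equal(unname(st2["W", "65-74", "DIABETES"]), 100)
  nxt2 <- step_cycle(st2, make_rates(m = 0.01, f = 0.01), make_paths(),
                     central, cfg)
  dead <- 100 * (1 - exp(-0.02))
  expect_equal(unname(nxt2["W", "65-74", "DEATH_T2D"]), dead / 2, tolerance = 1e-9)
  expect_equal(unname(nxt2["W", "65-74", "DEATH_OTHER"]), dead / 2, tolerance = 1e-9)

  # out-of-range probability is refused
  bad <- make_rates(i = -1)
  expect_error(step_cycle(st, bad, make_paths(), central, cfg), "\\[0, 1\\]")
})

test_that("aging moves a fixed fraction up one band and entrants top up", {
  cfg <- model_config(aging_fraction = 0.1)
  st <- initialize_states(make_pop_df(10), make_prev_list(), central)
  nxt <- step_cycle(st, make_rates(), make_paths(), central, cfg)
  # interior band: keeps 90% of its own, gains 10% of the younger band
  expect_equal(unname(nxt["M", "35-44", "HEALTHY"]), 10 * 0.9 + 10 * 0.1)
  # youngest band loses 10% with no entrants
  expect_equal(unname(nxt["M", "25-34", "HEALTHY"]), 9)
  # open last band keeps everyone and still receives from 65-74
  expect_equal(unname(nxt["M", "75+", "HEALTHY"]), 10 + 10 * 0.1)
  # entrants fill the youngest band up to the projection, never drain it
  nxt2 <- step_cycle(st, make_rates(), make_paths(), central, cfg,
                     young_target = c(M = 12, W = 5))
  expect_equal(unname(nxt2["M", "25-34", "HEALTHY"]), 12)
  expect_equal(unname(nxt2["W", "25-34", "HEALTHY"]), 9)  # already above 5
  expect_equal(unname(attr(nxt2, "entrants")), c(3, 0))
})

test_that("full fixture run conserves persons and absorbs deaths", {
  res <- run_markov(fix_pop, fix_prev)
  states <- attr(res, "states")
  first <- states[[1]]; last <- states[[length(states)]]
  ent <- attr(res, "cum_entrants")
  for (s in SEXES) {
    start_total <- sum(first[s, , ])
    end_total <- sum(last[s, , ])
    expect_equal(end_total, start_total + ent[[s]],
                 tolerance = 1e-9 * start_total)
  }
  # death states never decrease between cycles
  for (k in seq_len(length(states) - 1)) {
    expect_true(all(states[[k + 1]][, , "DEATH_T2D"] >=
                      states[[k]][, , "DEATH_T2D"] - 1e-12))
    expect_true(all(states[[k + 1]][, , "DEATH_OTHER"] >=
                      states[[k]][, , "DEATH_OTHER"] - 1e-12))
  }
  # all occupancies stay non-negative
  expect_true(all(vapply(states, function(st) all(st >= 0), logical(1))))
})

test_that("total prevalence is the population-weighted mean of the sexes", {
  res <- run_markov(fix_pop, fix_prev)
  for (y in c(2006, 2020, 2036)) {
    m <- res[res$year == y & res$sex == "M", ]
    w <- res[res$year == y & res$sex == "W", ]
    tot <- res[res$year == y & res$sex == "TOTAL", ]
    expect_equal(tot$prevalence,
                 weighted_total_prevalence(m$prevalence, w$prevalence,
                                           m$alive_millions, w$alive_millions),
                 tolerance = 1e-9)
  }
})

test_that("lower obesity paths never increase modelled prevalence", {
  s1 <- read_scenario(t2d_example("scenario1"))
  s2 <- read_scenario(t2d_example("scenario2"))
  base <- run_markov(fix_pop, fix_prev)
  r1 <- run_markov(fix_pop, fix_prev, scenario = s1)
  r2 <- run_markov(fix_pop, fix_prev, scenario = s2)
  for (s in c(SEXES, "TOTAL")) {
    pb <- base$prevalence[base$sex == s]
    p1 <- r1$prevalence[r1$sex == s]
    p2 <- r2$prevalence[r2$sex == s]
    expect_true(all(p2 <= p1 + 1e-12))
    expect_true(all(p1 <= pb + 1e-12))
  }
})

test_that("unit incidence RRs make obesity scenarios decorative", {
  p_null <- risk_params(rr_inc_obesity = c(1, 1, 1),
                        rr_inc_smoking = c(1, 1, 1))
  s2 <- read_scenario(t2d_example("scenario2"))
  base <- run_markov(fix_pop, fix_prev, params = p_null)
  scen <- run_markov(fix_pop, fix_prev, params = p_null, scenario = s2)
  expect_equal(scen$prevalence, base$prevalence, tolerance = 1e-12)
})

test_that("extreme bounds bracket the central run; degenerate triples collapse", {
  bounds <- extreme_bounds(function(set) {
    run_markov(fix_pop, fix_prev, param_set = set)
  })
  expect_true(all(bounds$min <= bounds$central + 1e-12))
  expect_true(all(bounds$central <= bounds$max + 1e-12))
  degen <- risk_params(rr_inc_obesity = c(3, 3, 3),
                       rr_inc_smoking = c(1.35, 1.35, 1.35),
                       rr_mort_t2d = c(2, 2, 2),
                       correction_factor = c(1.5, 1.5, 1.5))
  flatb <- extreme_bounds(function(set) {
    run_markov(fix_pop, fix_prev, params = degen, param_set = set)
  })
  expect_equal(flatb$min, flatb$max, tolerance = 1e-12)
})

test_that("prevented cases are prevalence differences times population", {
  base <- run_markov(fix_pop, fix_prev)
  expect_equal(unname(prevented_cases(base, base, fix_pop, 2036)), rep(0, 3))
  s2 <- run_markov(fix_pop, fix_prev,
                   scenario = read_scenario(t2d_example("scenario2")))
  pc <- prevented_cases(base, s2, fix_pop, 2036)
  expect_true(all(pc > 0))
  expect_equal(unname(pc["TOTAL"]), unname(pc["M"] + pc["W"]))
  expect_error(prevented_cases(base, s2, fix_pop, 2050), "cover year")
})

test_that("validation reproduces the initialization year exactly", {
  res <- run_markov(fix_pop, fix_prev)
  rep <- validate_series(res, fix_prev, fix_pop, factor = 1.5)
  expect_equal(rep$abs_diff[rep$year == 2006], 0, tolerance = 1e-12)
  expect_true(attr(rep, "mae") >= 0)
  # disjoint years are refused
  obs50 <- fix_prev[fix_prev$year == 2006, ]
  obs50$year <- 2050L
  obs50 <- age_sex_table(obs50, "prevalence_fraction")
  expect_error(validate_series(res, obs50, fix_pop), "overlapping")
})

test_that("a one-cycle horizon runs and equals a single step", {
  res <- run_markov(fix_pop, fix_prev, config = model_config(end_year = 2007))
  expect_equal(sort(unique(res$year)), c(2006L, 2007L))
  expect_equal(nrow(res), 6L)
  full <- run_markov(fix_pop, fix_prev)
  expect_equal(res$prevalence[res$year == 2007],
               full$prevalence[full$year == 2007], tolerance = 1e-12)
})
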