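---
title: "Forecasting type 2 diabetes prevalence with a multistate Markov cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting type 2 diabetes prevalence with a multistate Markov cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2dmarkov)
```

## The model

`t2dmarkov` projects type 2 diabetes (T2D) prevalence over a multi-decade
horizon by combining three ingredients: a population projection by sex and
age band, observed prevalence trends of the major modifiable risk factors
(obesity and smoking), and a cross-sectional diabetes prevalence profile
from which age-specific incidence is back-calculated.

The population aged 25 and over is tracked per sex in six ten-year age
bands (25–34 … 65–74, 75+), each divided into six states:

* four alive pools — **healthy** (non-obese, non-smoking, non-diabetic),
  **obese**, **smoker**, and **diabetes**;
* two absorbing death states — **diabetes-related death** and **other
  death**, kept separate as competing risks.

Each annual cycle applies, in this order:

1. **Incidence.** The healthy pool develops diabetes with probability
   $1 - e^{-i}$, where $i$ is the age/sex incidence hazard; the obese and
   smoker pools face the elevated hazards $i \cdot RR_{ob}$ and
   $i \cdot RR_{sm}$.
2. **Mortality.** Non-diabetic states die at $1 - e^{-m}$ where $m$ is the
   non-diseased all-cause hazard; the diabetes pool dies at
   $1 - e^{-(m+f)}$, where $f$ is the excess (case) fatality hazard, and
   the excess share $f/(m+f)$ of those deaths is booked to the
   diabetes-related death state.
3. **Risk-factor re-balancing.** The alive non-diabetic population is
   re-partitioned so that the obese and smoker pool shares track the
   projected risk-factor paths for the next year. The diabetes pool is
   never re-balanced: remission is zero.
4. **Aging.** A fixed fraction (1/10 per year, the uniform-age
   approximation for ten-year bands) of every alive state moves up one
   band; the open 75+ band retains its members. New 25-year-olds enter
   the youngest band, topping it up to the population projection, and are
   distributed over that band's current pool proportions.

Hazards are converted to probabilities with $1 - e^{-\text{rate}}$
throughout, which keeps every transition probability in $[0,1]$ for any
non-negative hazard.

### Overlap partition

Survey prevalences of obesity, smoking and diabetes overlap. The starting
states (and the re-balancing step) remove overlap in three fixed steps:

1. obese smokers, estimated under independence as
   $p_{sm} \cdot p_{ob}$, are removed from the smoker pool;
2. diabetics attributable to obesity, $PAF_{ob} \cdot p_{dm}$, are removed
   from the obese pool;
3. diabetics attributable to smoking, $PAF_{sm} \cdot p_{dm}$, are removed
   from the remaining smoker pool.

The attributable fractions use Levin's formula for a binary exposure,
$PAF = \frac{p(RR-1)}{1 + p(RR-1)}$, with the *incidence* relative risks
and the current exposure prevalences. Attributable diabetics are
subtracted from the risk-factor pools, not from the diabetes pool, so the
diabetes pool always carries the full diabetes prevalence. Independence
(the product rule) for the obese-smoker overlap is a deliberate choice:
conditional membership probabilities would require joint survey
micro-data that aggregated prevalence tables do not provide.

### Incidence back-calculation

Age-specific incidence is rarely observed; the package recovers it from a
cross-sectional prevalence profile with a zero-remission illness–death
model. Writing $S(a)$ and $C(a)$ for the susceptible and diseased cohort
fractions,

$$\frac{dS}{da} = -(i + m_h)\,S, \qquad
  \frac{dC}{da} = i\,S - (m_h + f)\,C,$$

with prevalence $p = C/(S+C)$. Differentiating the ratio gives the
inversion used by `back_calculate_incidence()`:

$$i(a) = \frac{p'(a)}{1 - p(a)} + p(a) f(a),$$

with $p'$ from central differences (one-sided at the grid ends) and
negative values floored at zero. The mortality split uses the usual
relative risk $RR$ of mortality (diseased vs healthy):
$m_h = m_{all} / (1 + p(RR - 1))$ and $m_d = RR \cdot m_h$, the same
relationship as the prevalence-adjusted relative risk
$RR_{adj} = RR/(p \cdot RR + 1 - p)$ exposed by `adjust_rr()`.

`forward_simulate()` integrates the same two equations with a fixed-step
fourth-order Runge–Kutta scheme at the grid resolution and is the
independent oracle for the inversion: the test suite checks that
back-calculation recovers constant, linear and logistic incidence shapes
within 2% relative error at interior ages for mortality relative risks
between 1 and 3.

Band-level prevalence is expanded to a 1-year grid (ages 25–100) by
piecewise-linear interpolation through the band midpoints, with the open
75+ band represented by age 82; derivatives on six points alone would be
too coarse. Hazards are aggregated back to bands with survival weights
from the mortality curve so the oldest ages of the open band do not
dominate. Incidence is calibrated once, on the 2010 cross-section
(interpolated from the packaged 2006/2020 anchors), and held fixed over
the horizon.

### All-cause mortality input

The model needs an all-cause mortality schedule, which prevalence surveys
do not supply. The packaged default (`default_mortality_profile()`) is a
**synthetic** Gompertz hazard, $m(a) = m_0 e^{b(a-25)}$, with sex-specific
level and slope chosen to give plausible adult hazards for a middle-income
country (men ≈ 0.0015/yr at 25 rising to ≈ 0.08/yr at 80; women lower).
Users with a real life table should pass it via `read_life_table()` and
`model_config(mortality = ...)`; all downstream machinery is unchanged.

## Parameters

All epidemiological constants travel as `(min, central, max)` triples in
`risk_params()` so the extreme-value analysis can re-run the model at the
joint bounds:

| parameter | default (min, central, max) | meaning |
|---|---|---|
| `rr_inc_obesity` | (2, 3, 4) | T2D incidence RR, obese (BMI > 30) vs not |
| `rr_inc_smoking` | (1.3, 1.35, 1.4) | T2D incidence RR, smoker vs not (30–40% excess) |
| `rr_mort_t2d` | (1.5, 2, 2.5) | all-cause mortality RR, diabetic vs healthy |
| `remission_rate` | (0, 0, 0) | fixed: T2D treated as irreversible |
| `correction_factor` | (1.2, 1.5, 2) | self-report under-diagnosis multiplier |

The correction factor reflects that roughly half of true cases go
unreported in self-report surveys; 1.5 is the central multiplier, with
2.0 as the pessimistic bound (50% under-reporting exactly) and 1.2 as the
optimistic one. It is applied both to the initialization-year prevalence
and to every year of the validation comparison — applying it only at
initialization is possible by passing `factor = 1` to
`validate_series()`.

## Risk-factor trends and scenarios

Observed obesity and smoking prevalences are extrapolated linearly, per
sex, with a pooled OLS regression: one intercept per age band (fixed
effects) and a single shared calendar-year slope. Pooling the bands
increases the information behind the common time effect; a per-band
independent-slopes variant (`pooled = FALSE`) is available for
sensitivity. Projections are clamped to $[0,1]$ and clamping is flagged —
smoking projects to near zero in some bands.

Policy scenarios modify the obesity path only (projected smoking declines
so far on its own that a smoking scenario would add almost nothing). A
"−1% per year" scenario is interpreted **relatively**: from the scenario
start year the path is $v_{start}(1 + c)^t$ with $c = -0.01$, i.e. a
multiplier of $0.99^{16} \approx 0.85$ over 16 years (and
$0.95^{16} \approx 0.44$ for the −5%/yr variant). Relative decline keeps
prevalence positive at any horizon and is the common reading in this
model family; an `absolute_pp` mode (percentage-point arithmetic, floored
at zero) is available in `scenario_spec()` for the alternative reading.

## Sensitivity and validation

`extreme_bounds()` re-runs the whole model with *all* parameters at their
minima, centres and maxima — the conservative extreme-scenario approach —
and reports the per-cell envelope of the three runs. The envelope is
taken after evaluation rather than assuming monotonicity in the
parameters, so the bounds always bracket the central value.

`validate_series()` compares the modelled total prevalence with the
corrected observed series in every overlapping year and reports absolute
and relative differences plus the mean absolute error. At the
initialization year the two agree by construction, which doubles as a
consistency check of the initialization path.

## Synthetic data

`synthetic_spec()` + the generators emulate the two input streams with
known ground truth:

* **prevalence panel** — linear latent trends per (factor, sex, band)
  observed through binomial sampling noise with `survey_n` respondents
  per cell, the noise model of a simple random telephone survey. Design
  effects, weighting and self-report bias beyond the global correction
  factor are *not* emulated, so passing recovery tests says nothing about
  those error sources in real data;
* **population projection** — deterministic exponential growth per band,
  with faster growth in older bands to mimic demographic aging.

`generate_ground_truth_run()` produces a noiseless reference trajectory;
the test suite perturbs the panel at `survey_n = 5000` over 100 seeds and
requires the 2036 total prevalence to stay within 1 percentage point of
the reference in at least 90 of them.

## Numerical choices and problem sizes

* Age grid 25–100 at 1-year resolution (76 points); RK4 forward
  integration at that step; central differences for the inversion.
* 31 annual cycles (2006–2036), 2 sexes × 6 bands × 6 states.
* Conservation (alive + cumulative deaths = initial + entrants) holds to
  1e-9 relative and is asserted per sex in the tests.
* Re-balancing uses a floored variant of the overlap partition: under
  extreme parameter sets the literal subtraction can turn a pool
  negative, in which case the pool is floored at zero and the remainder
  assigned to the healthy pool (shrinking risk-factor pools
  proportionally if diabetes alone exceeds the population). The strict
  partition, which raises an error instead, is what `partition_states()`
  exposes by default.
* Monte-Carlo sizes: 100 seeds for the recovery experiment, 10⁴-point
  grids for the closed-form oracle checks.

## Known limitations

* The packaged prevalence fixture carries the two printed survey anchors
  (2006 and 2020), so fitted slopes equal endpoint differences; with the
  full annual series the pooled OLS uses all 15 years, and steeper recent
  declines (notably in smoking) would produce steeper projections.
* The default mortality schedule is synthetic; absolute case counts and
  death-state totals inherit its uncertainty.
* Counts are reported in millions of persons; prevalences as fractions
  (printed as % in the summaries).
* No migration, no microsimulation of individuals, no diabetes
  complications or costs; obesity is the binary BMI > 30 pool, with no
  continuous BMI modelling.
* Incidence is held at its calibration-year profile for the whole
  horizon; if true incidence drifts, long-horizon prevalence drifts with
  it. Re-calibration per cycle would require annual prevalence
  cross-sections of trusted comparability.

## A worked run

```{r run, eval = FALSE}
pop <- brazil_population()
prev <- brazil_prevalence()
baseline <- run_markov(pop, prev)
scenario2 <- run_markov(pop, prev,
                        scenario = read_scenario(t2d_example("scenario2")))
subset(baseline, year %in% c(2006, 2020, 2036))
prevented_cases(baseline, scenario2, pop, 2036)
bounds <- extreme_bounds(function(set) run_markov(pop, prev, param_set = set))
head(subset(bounds, metric == "prevalence"))
```
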