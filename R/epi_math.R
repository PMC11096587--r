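# Closed-form epidemiological formulas: mortality relative-risk adjustment,
# Levin's attributable fraction, the risk-factor overlap partition, and the
# self-report correction.

#' Adjust a mortality relative risk for disease prevalence
#'
#' Converts the usual relative risk of mortality (diseased vs healthy) into
#' the relative risk of the diseased vs the *total* population:
#' `RRadj = RR / (p * RR + 1 - p)`. With healthy mortality 1 and diseased
#' mortality RR, population mortality is `p * RR + (1 - p)`, so RRadj is the
#' diseased-to-population mortality ratio.
#'
#' @param rr Usual mortality relative risk (> 0).
#' @param p Disease prevalence fraction in \[0, 1\].
#' @return Adjusted relative risk; `<= rr`, with equality iff `p = 0` or
#'   `rr = 1`. Vectorized.
#' @export
adjust_rr <- function(rr, p) {
  if (any(rr <= 0)) stop("adjust_rr: rr must be > 0")
  if (any(p < 0 | p > 1)) stop("adjust_rr: p must lie in [0, 1]")
  rr / (p * rr + 1 - p)
}

#' Levin population attributable fraction
#'
#' Fraction of cases attributable to a binary exposure:
#' `PAF = p (RR - 1) / (1 + p (RR - 1))` for exposure prevalence `p` and
#' incidence relative risk `RR`.
#'
#' @param p_exposed Exposure prevalence fraction in \[0, 1\].
#' @param rr Incidence relative risk (> 0).
#' @return Attributable fraction; in \[0, 1) for `rr >= 1`. Vectorized.
#' @export
levin_par <- function(p_exposed, rr) {
  if (any(p_exposed < 0 | p_exposed > 1)) {
    stop("levin_par: p_exposed must lie in [0, 1]")
  }
  if (any(rr <= 0)) stop("levin_par: rr must be > 0")
  p_exposed * (rr - 1) / (1 + p_exposed * (rr - 1))
}

#' Partition the alive population into the four model pools
#'
#' Removes overlaps between the healthy, obese, smoker and diabetes pools
#' in three fixed steps:
#' 1. obese smokers are removed from the smoker pool assuming independence
#'    (`smoker' = p_smoker - p_smoker * p_obese`);
#' 2. diabetics attributable to obesity (`par_obesity * p_t2d`) are removed
#'    from the obese pool;
#' 3. diabetics attributable to smoking (`par_smoking * p_t2d`) are removed
#'    from the reduced smoker pool.
#' The diabetes pool keeps the full diabetes prevalence; healthy is the
#' remainder. Attributable diabetics are subtracted from the risk-factor
#' pools, never from the diabetes pool.
#'
#' @param p_obese,p_smoker,p_t2d Prevalence fractions of obesity, smoking
#'   and diabetes in the population.
#' @param par_obesity,par_smoking Attributable fractions of diabetes for
#'   each exposure (see [levin_par()]).
#' @param floor If `TRUE`, pools that would go negative are floored at zero
#'   (and healthy kept non-negative by proportional shrink) instead of
#'   raising an error; used by the cycle engine where extreme parameter
#'   sets can make the literal subtraction infeasible.
#' @return List with class `state_fractions`: `healthy`, `obese`, `smoker`,
#'   `diabetes`, summing to exactly 1.
#' @export
partition_states <- function(p_obese, p_smoker, p_t2d,
                             par_obesity, par_smoking, floor = FALSE) {
  args <- c(p_obese = p_obese, p_smoker = p_smoker, p_t2d = p_t2d,
            par_obesity = par_obesity, par_smoking = par_smoking)
  if (any(args < 0 | args > 1)) {
    stop("partition_states: all inputs must lie in [0, 1]")
  }
  smoker1 <- p_smoker - p_smoker * p_obese          # step 1: obese smokers out
  obese1 <- p_obese - par_obesity * p_t2d           # step 2: obesity-attributable diabetics out
  smoker2 <- smoker1 - par_smoking * p_t2d          # step 3: smoking-attributable diabetics out
  if (!floor) {
    if (obese1 < 0) {
      stop("partition_states: infeasible overlap at step 2 (obese pool negative)")
    }
    if (smoker2 < 0) {
      stop("partition_states: infeasible overlap at step 3 (smoker pool negative)")
    }
  } else {
    obese1 <- max(obese1, 0)
    smoker2 <- max(smoker2, 0)
  }
  healthy <- 1 - p_t2d - obese1 - smoker2
  if (healthy < 0) {
    if (!floor) {
      stop("partition_states: infeasible overlap (healthy pool negative)")
    }
    # shrink the risk-factor pools proportionally to fit beside diabetes
    room <- max(1 - p_t2d, 0)
    tot <- obese1 + smoker2
    if (tot > 0) {
      obese1 <- obese1 * room / tot
      smoker2 <- smoker2 * room / tot
    }
    healthy <- 1 - p_t2d - obese1 - smoker2
    healthy <- max(healthy, 0)
  }
  structure(list(healthy = healthy, obese = obese1,
                 smoker = smoker2, diabetes = p_t2d),
            class = "state_fractions")
}

#' Correct self-reported prevalence for under-reporting
#'
#' @param raw_prevalence Self-reported prevalence fraction (>= 0).
#' @param factor Correction multiplier (> 0); default 1.5, i.e. 50%
#'   under-reporting.
#' @return `raw_prevalence * factor`; an error if the product exceeds 1.
#' @export
apply_correction <- function(raw_prevalence, factor = 1.5) {
  if (any(raw_prevalence < 0)) {
    stop("apply_correction: raw_prevalence must be >= 0")
  }
  if (any(factor <= 0)) stop("apply_correction: factor must be > 0")
  out <- raw_prevalence * factor
  if (any(out > 1)) {
    stop("apply_correction: corrected prevalence exceeds 1")
  }
  out
}
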