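# Simulation-study utilities: single-replicate parameter recovery and
# nonlinearity detection runs against the synthetic generator.

# Shared plumbing: simulate, build the incident cohort for the primary
# outcome, and return the bare counting-process table plus metadata.
.replicate_tables <- function(n_participants, seed, hazard_spec,
                              baseline_monthly_hazard,
                              covariate_missingness = NULL) {
  cfg <- sim_config(n_participants = n_participants, seed = seed,
                    hazard_spec = hazard_spec,
                    baseline_monthly_hazard = baseline_monthly_hazard,
                    n_null_phecodes = 0,
                    covariate_missingness = covariate_missingness)
  cohort <- gen_cohort(cfg)
  daily <- gen_daily_series(cohort, cfg)
  ev <- gen_outcome_events(cohort, daily, cfg)
  monthly <- monthly_exposures_all(daily)
  pe <- map_events_to_phecodes(ev$conditions, ev$map)
  cens <- censoring_date(ev$encounters, ev$conditions)
  mon <- data.frame(person_id = cohort$truth$person_id,
                    start_date = cohort$truth$start_date,
                    stringsAsFactors = FALSE)
  co <- build_incident_cohort(pe, mon, cens, "401.1")
  cp0 <- build_counting_process(co, monthly, covariates = NULL)
  list(cfg = cfg, cohort = cohort, cp0 = cp0,
       ground_truth = ev$ground_truth)
}

#' One parameter-recovery replicate: pooled log hazard ratio per 1,000 steps
#'
#' Simulates a cohort with a log-linear protective step effect, imputes
#' missing covariates (predictive mean matching, `m` imputations), fits the
#' time-varying Cox model with a linear exposure adjusted for age, sex and
#' race in each completed dataset, and pools with Rubin's rules.
#'
#' @param n_participants cohort size.
#' @param seed replicate seed.
#' @param hr_per_1000 true hazard ratio per 1,000 steps/day.
#' @param m imputations.
#' @param baseline_monthly_hazard baseline hazard per month.
#' @return list: `estimate` (pooled log HR per 1,000 steps), `se`,
#'   `ci_low`, `ci_high`, `truth`, `covered`, `n_events`.
#' @export
recovery_replicate <- function(n_participants, seed, hr_per_1000 = 0.80,
                               m = 5, baseline_monthly_hazard = 0.0025) {
  tb <- .replicate_tables(n_participants, seed,
                          hazard_loglinear(hr_per_1000),
                          baseline_monthly_hazard,
                          covariate_missingness = c(race = 0.054,
                                                    sex = 0.014))
  imp <- pmm_impute(tb$cohort$covariates[, c("person_id", "age", "sex",
                                             "race")],
                    m = m, seed = child_seed(seed, "rec-imp"))
  est <- vapply(imp$imputations, function(cd) {
    cp <- cbind(tb$cp0, cd[match(tb$cp0$person_id, cd$person_id),
                           c("age", "sex", "race")])
    f <- fit_cox_tv(cp, covariates = c("age", "sex", "race"))
    c(f$coef[["steps"]] * 1000, 1e6 * f$vcov["steps", "steps"])
  }, numeric(2))
  pooled <- rubin_pool(est[1, ], est[2, ])
  truth <- log(hr_per_1000)
  list(estimate = pooled$q_bar, se = pooled$se,
       ci_low = pooled$ci_low, ci_high = pooled$ci_high, truth = truth,
       covered = pooled$ci_low <= truth && truth <= pooled$ci_high,
       n_events = sum(tb$cp0$event))
}

#' One nonlinearity-detection replicate
#'
#' Simulates a cohort under the supplied hazard shape, fits restricted
#' cubic spline Cox models with 3, 4 and 5 knots (age/sex/race adjusted,
#' complete covariates), selects by AIC, and returns the chunk tests of the
#' selected fit.
#'
#' @param n_participants cohort size.
#' @param seed replicate seed.
#' @param hazard_spec a [hazard_loglinear()], [hazard_plateau()] or
#'   [hazard_null()] truth.
#' @param baseline_monthly_hazard baseline hazard per month.
#' @param knot_choices candidate knot counts.
#' @return list: `k_selected`, `p_nonlinear`, `p_overall`, `n_events`.
#' @export
nonlinearity_replicate <- function(n_participants, seed, hazard_spec,
                                   baseline_monthly_hazard = 0.0025,
                                   knot_choices = c(3, 4, 5)) {
  tb <- .replicate_tables(n_participants, seed, hazard_spec,
                          baseline_monthly_hazard,
                          covariate_missingness = 0)
  cd <- tb$cohort$covariates_complete
  cp <- cbind(tb$cp0, cd[match(tb$cp0$person_id, cd$person_id),
                         c("age", "sex", "race")])
  fits <- lapply(knot_choices, function(k)
    fit_cox_tv(cp, knots = k, covariates = c("age", "sex", "race")))
  sel <- select_by_aic(fits)
  list(k_selected = length(sel$knots),
       p_nonlinear = wald_chunk_test(sel, "nonlinear")$p_value,
       p_overall = wald_chunk_test(sel, "exposure")$p_value,
       n_events = sum(cp$event))
}

#' One falsification replicate: step-independent outcome
#'
#' Simulates a cohort whose events are independent of steps and returns the
#' overall exposure chunk-test p-value from a 3-knot spline fit; across
#' replicates these should be uniform on (0, 1).
#'
#' @param n_participants cohort size.
#' @param seed replicate seed.
#' @param baseline_monthly_hazard baseline hazard per month.
#' @return list: `p_overall`, `n_events`.
#' @export
falsification_replicate <- function(n_participants, seed,
                                    baseline_monthly_hazard = 0.004) {
  tb <- .replicate_tables(n_participants, seed, hazard_null(),
                          baseline_monthly_hazard,
                          covariate_missingness = 0)
  cd <- tb$cohort$covariates_complete
  cp <- cbind(tb$cp0, cd[match(tb$cp0$person_id, cd$person_id),
                         c("age", "sex", "race")])
  f <- fit_cox_tv(cp, knots = 3, covariates = c("age", "sex", "race"))
  list(p_overall = wald_chunk_test(f, "exposure")$p_value,
       n_events = sum(cp$event))
}
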