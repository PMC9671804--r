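# Synthetic cohort generator: determinism, calibrated distributions,
# bookkeeping identities, and the phecode map fixture.

test_that("identical configs give byte-identical outputs", {
  cfg <- sim_config(n_participants = 40, seed = 7, monitoring_years = 1,
                    vary_duration = FALSE, n_null_phecodes = 2)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$daily, b$daily)
  expect_identical(a$conditions, b$conditions)
  expect_identical(a$encounters, b$encounters)
})

test_that("covariate missingness is injected at the configured MCAR rate", {
  cfg0 <- sim_config(n_participants = 200, seed = 5,
                     covariate_missingness = 0)
  c0 <- gen_cohort(cfg0)
  expect_false(anyNA(c0$covariates))

  cfg <- sim_config(n_participants = 5000, seed = 5,
                    covariate_missingness = 0.2)
  co <- gen_cohort(cfg)
  for (v in c("race", "sex", "bmi", "education")) {
    expect_lt(abs(mean(is.na(co$covariates[[v]])) - 0.2), 0.02)
  }
  expect_false(anyNA(co$covariates_complete))
  expect_error(sim_config(5, covariate_missingness = 1.4), "0, 1")
  expect_error(sim_config(0), "n_participants")
})

test_that("person-level and daily step distributions match their targets", {
  cfg <- sim_config(n_participants = 2000, seed = 9)
  co <- gen_cohort(cfg)
  # median of person-level mean daily steps near 7,731
  expect_lt(abs(median(co$truth$step_level) / 7731 - 1), 0.05)
  # monitoring duration: median near 4 years
  expect_lt(abs(median(co$truth$duration_years) - 4), 0.35)

  daily <- gen_daily_series(co, sim_config(n_participants = 2000, seed = 9))
  w <- daily$worn
  # realised worn-day mean per person tracks the person level
  pm <- tapply(daily$total_steps[w], daily$person_id[w], mean)
  lvl <- co$truth$step_level[match(names(pm), co$truth$person_id)]
  expect_lt(abs(mean(pm / lvl) - 1), 0.03)
  # bout metrics internally consistent
  expect_true(all(daily$bout_steps_100 <= daily$bout_steps_60 + 1e-9))
  expect_true(all(daily$n_bout_minutes_100 <= daily$n_bout_minutes_60))
})

test_that("minute streams honour non-wear, hit targets, and re-aggregate", {
  cfg_off <- sim_config(n_participants = 1, seed = 2, frac_nonwear_days = 0.99)
  p <- list(person_id = "T1", step_level = 8000, n_days = 30,
            start_date = as.Date("2020-01-01"))
  cfg_off$frac_nonwear_days <- 1 - 1e-12  # effectively all non-wear
  s_off <- gen_minute_stream(p, cfg_off)
  expect_true(all(s_off$steps == 0))

  cfg <- sim_config(n_participants = 1, seed = 2, frac_nonwear_days = 0)
  s <- gen_minute_stream(list(person_id = "T2", step_level = 8000,
                              n_days = 1000,
                              start_date = as.Date("2020-01-01")), cfg)
  truth <- attr(s, "daily_truth")
  # law of large numbers: mean worn-day total within 5% of the 8,000 target
  expect_lt(abs(mean(truth$total_steps[truth$worn]) / 8000 - 1), 0.05)

  # bookkeeping identity: summarize_days totals equal the generator's truth
  s150 <- gen_minute_stream(list(person_id = "T3", step_level = 9000,
                                 n_days = 120,
                                 start_date = as.Date("2020-01-01")), cfg)
  ds <- summarize_days(s150)
  tr <- attr(s150, "daily_truth")
  expect_equal(ds$total_steps, tr$total_steps)
  # and any pooled bout cadence respects the threshold floor
  iv <- ds[ds$is_valid, ]
  if (sum(iv$n_bout_minutes_60) > 0) {
    expect_gte(sum(iv$bout_steps_60) / sum(iv$n_bout_minutes_60), 60)
  }
})

test_that("the phecode map fixture covers every emitted code exactly once", {
  cfg <- sim_config(n_participants = 120, seed = 13, n_null_phecodes = 4)
  sim <- simulate_study(cfg)
  map <- sim$map
  key <- paste(map$vocabulary, map$code)
  expect_false(anyDuplicated(key) > 0)
  emitted <- unique(paste(sim$conditions$vocabulary, sim$conditions$code))
  emitted <- setdiff(emitted, "ICD10CM Z00.0")  # deliberate unmapped noise
  expect_true(all(emitted %in% key))
  # combination flags present for the folded phecode pairs
  expect_equal(map$combine_to[map$phecode == "250.24"], "250.2")
  expect_equal(map$combine_to[map$phecode == "327.23"], "327.3")
  # two distinct ICD codes map to one phecode
  expect_gte(sum(map$phecode == "401.1"), 2)

  # file round trip
  tf <- file.path(tempdir(), "map.csv")
  utils::write.csv(map, tf, row.names = FALSE)
  back <- utils::read.csv(tf, stringsAsFactors = FALSE,
                          colClasses = c(phecode = "character",
                                         combine_to = "character"))
  back$combine_to[back$combine_to == ""] <- NA_character_
  expect_equal(back$phecode, map$phecode)
  expect_equal(back$code, map$code)
})

test_that("null baseline hazard of zero yields no events", {
  cfg <- sim_config(n_participants = 60, seed = 21,
                    baseline_monthly_hazard = 0, n_null_phecodes = 0,
                    frac_prevalent = 0, frac_washout = 0)
  sim <- simulate_study(cfg)
  gt <- sim$ground_truth$events$hypertension
  expect_true(all(is.na(gt$event_month)))
})

test_that("the privacy date shift leaves monitoring-relative data unchanged", {
  base <- sim_config(n_participants = 50, seed = 31, n_null_phecodes = 0)
  shifted <- sim_config(n_participants = 50, seed = 31, n_null_phecodes = 0,
                        date_shift = TRUE)
  a <- simulate_study(base)
  b <- simulate_study(shifted)
  # same relative daily stream and event months, different calendar dates
  expect_identical(a$daily$total_steps, b$daily$total_steps)
  expect_identical(a$ground_truth$events$hypertension$event_month,
                   b$ground_truth$events$hypertension$event_month)
  ma <- monthly_exposures_all(a$daily)
  mb <- monthly_exposures_all(b$daily)
  expect_equal(ma$running_mean_steps, mb$running_mean_steps)
})

test_that("measured invalid-month fraction matches the closed-form rate", {
  cfg <- sim_config(n_participants = 400, seed = 41, n_null_phecodes = 0)
  co <- gen_cohort(cfg)
  daily <- gen_daily_series(co, cfg)
  monthly <- monthly_exposures_all(daily)
  expect_lt(abs(mean(!monthly$is_valid_month) -
                  expected_invalid_month_rate(cfg)), 0.03)
})

test_that("loglinear events track the integrated-hazard tertile prediction", {
  cfg <- sim_config(n_participants = 5000, seed = 51,
                    monitoring_years = 3, vary_duration = FALSE,
                    hazard_spec = hazard_loglinear(0.80),
                    n_null_phecodes = 0, frac_prevalent = 0,
                    frac_washout = 0)
  co <- gen_cohort(cfg)
  daily <- gen_daily_series(co, cfg)
  ev <- gen_outcome_events(co, daily, cfg)
  gt <- ev$ground_truth$events$hypertension
  lvl <- co$truth$step_level
  ter <- cut(lvl, quantile(lvl, 0:3 / 3), include.lowest = TRUE,
             labels = c("low", "mid", "high"))
  inc <- tapply(!is.na(gt$event_month), ter, mean)
  # predicted cumulative incidence per tertile from the true hazard
  hs <- cfg$hazard_spec
  months <- 36
  pred <- tapply(1 - exp(-cfg$baseline_monthly_hazard *
                           exp(hs$lp(lvl)) * months), ter, mean)
  for (g in c("low", "mid", "high")) {
    expect_lt(abs(inc[[g]] - pred[[g]]), 3.5 * sqrt(pred[[g]] / (5000 / 3)))
  }
  expect_gt(inc[["low"]], inc[["high"]])  # protective direction
})
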