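# Phecode mapping, washout/censoring logic, counting-process construction.

fix_monitoring <- data.frame(
  person_id = c("A", "B", "C", "D"),
  start_date = as.Date("2020-01-01"), stringsAsFactors = FALSE)

fix_conditions <- data.frame(
  person_id = c("A", "B", "B", "C", "D"),
  date = as.Date("2020-01-01") + c(90, 600, 700, 100, -50),
  code = c("I10", "I10", "401.1", "ZZZ", "I10"),
  vocabulary = c("ICD10CM", "ICD10CM", "ICD9CM", "ICD10CM", "ICD10CM"),
  stringsAsFactors = FALSE)

fix_encounters <- data.frame(
  person_id = rep(c("A", "B", "C", "D"), each = 3),
  date = as.Date("2020-01-01") + rep(c(0, 400, 1080), 4),
  domain = rep(c("measurement", "lab", "procedure"), 4),
  stringsAsFactors = FALSE)

test_that("ICD events map to earliest phecode occurrences, unmapped logged", {
  map <- gen_phecode_map_fixture(0)
  pe <- map_events_to_phecodes(fix_conditions, map)
  expect_equal(attr(pe, "n_unmapped"), 1)          # the ZZZ code
  expect_false("C" %in% pe$person_id)
  # two ICD codes, same phecode: earliest date kept
  b <- pe[pe$person_id == "B", ]
  expect_equal(nrow(b), 1)
  expect_equal(b$first_date, as.Date("2020-01-01") + 600)
  expect_error(map_events_to_phecodes(
    transform(fix_conditions, vocabulary = "SNOMED"), map), "vocabulary")
})

test_that("mapped event counts equal an independent join on random fixtures", {
  set.seed(71)
  map <- gen_phecode_map_fixture(5)
  cond <- data.frame(
    person_id = sample(LETTERS[1:6], 80, TRUE),
    date = as.Date("2020-01-01") + sample(0:900, 80, TRUE),
    code = sample(c(map$code, "QQQ"), 80, TRUE),
    vocabulary = "ICD10CM", stringsAsFactors = FALSE)
  cond$vocabulary <- map$vocabulary[match(cond$code, map$code)]
  cond$vocabulary[is.na(cond$vocabulary)] <- "ICD10CM"
  pe <- map_events_to_phecodes(cond, map)
  mg <- merge(cond, map, by = c("vocabulary", "code"))
  expect_equal(nrow(pe), nrow(unique(mg[, c("person_id", "phecode")])))
  expect_equal(attr(pe, "n_unmapped"), sum(cond$code == "QQQ"))
})

test_that("censoring date is the max across encounter domains", {
  cd <- censoring_date(data.frame(
    person_id = "x", date = as.Date(c("2020-01-01", "2020-03-05",
                                      "2020-02-02")),
    domain = c("measurement", "procedure", "lab")))
  expect_equal(cd$censor_date, as.Date("2020-03-05"))
  one <- censoring_date(data.frame(person_id = "y",
                                   date = as.Date("2021-07-07"),
                                   domain = "condition"))
  expect_equal(one$censor_date, as.Date("2021-07-07"))
  # condition codes count as encounters
  cd2 <- censoring_date(fix_encounters, fix_conditions)
  expect_equal(cd2$censor_date[cd2$person_id == "B"],
               as.Date("2020-01-01") + 1080)
  set.seed(72)
  enc <- data.frame(person_id = sample(c("p", "q"), 50, TRUE),
                    date = as.Date("2020-01-01") + sample(0:999, 50),
                    domain = sample(c("measurement", "lab", "procedure",
                                      "condition"), 50, TRUE))
  cd3 <- censoring_date(enc)
  for (p in c("p", "q")) {
    expect_equal(cd3$censor_date[cd3$person_id == p],
                 max(enc$date[enc$person_id == p]))
  }
})

test_that("washout, prevalence and censoring assemble the incident cohort", {
  map <- gen_phecode_map_fixture(0)
  pe <- map_events_to_phecodes(fix_conditions, map)
  cens <- censoring_date(fix_encounters, fix_conditions)
  co <- build_incident_cohort(pe, fix_monitoring, cens, "401.1")
  # A: occurrence at month 3 -> excluded (within washout)
  expect_equal(co$excluded$reason[co$excluded$person_id == "A"],
               "occurrence_in_washout")
  # D: occurrence before monitoring start -> prevalent exclusion
  expect_equal(co$excluded$reason[co$excluded$person_id == "D"],
               "prevalent_before_monitoring")
  # B: event at day 600 -> month 20
  b <- co$cohort[co$cohort$person_id == "B", ]
  expect_equal(b$event, 1L)
  expect_equal(b$exit, 20)
  expect_equal(b$entry, 6)
  # C: no mapped occurrence -> censored at last encounter (day 1080 = month 36)
  cc <- co$cohort[co$cohort$person_id == "C", ]
  expect_equal(cc$event, 0L)
  expect_equal(cc$exit, 36)
})

test_that("combined phecodes are analysed as one outcome", {
  map <- gen_phecode_map_fixture(0)
  cond <- data.frame(person_id = c("A", "A"),
                     date = as.Date("2020-01-01") + c(400, 250),
                     code = c("G47.30", "G47.33"),
                     vocabulary = "ICD10CM", stringsAsFactors = FALSE)
  pe <- map_events_to_phecodes(cond, map)
  cens <- data.frame(person_id = "A",
                     censor_date = as.Date("2020-01-01") + 900)
  co <- build_incident_cohort(pe, fix_monitoring[1, ], cens,
                              c("327.3", "327.23"))
  # earliest qualifying occurrence across the pair: day 250
  expect_equal(co$cohort$exit, 250 / 30)
})

# Minimal monthly-exposure table builder: valid months with given means.
make_monthly <- function(person_id, means, valid = TRUE) {
  n <- length(means)
  valid <- rep_len(valid, n)
  nv <- ifelse(valid, 20L, 0L)
  run <- cumsum(ifelse(valid, means, 0) * nv) / pmax(cumsum(nv * valid), 1)
  run[cumsum(nv * valid) == 0] <- NA
  lvm <- rep(NA_real_, n)
  last <- NA_real_
  for (i in seq_len(n)) {
    if (valid[i]) last <- means[i]
    lvm[i] <- last
  }
  data.frame(person_id = person_id, month_index = seq_len(n) - 1L,
             n_valid_days = nv, mean_steps = ifelse(valid, means, NA),
             mean_wear_hours = 12, is_valid_month = valid,
             running_mean_steps = run, last_valid_mean = lvm,
             stringsAsFactors = FALSE)
}

test_that("counting process: 12 valid months, event at month 12 -> 6 rows", {
  co <- list(cohort = data.frame(person_id = "B", entry = 6, exit = 12,
                                 event = 1L, stringsAsFactors = FALSE),
             excluded = data.frame(), washout_months = 6)
  monthly <- make_monthly("B", rep(8000, 13))
  cp <- build_counting_process(co, monthly)
  expect_equal(nrow(cp), 6)
  expect_equal(cp$start, 6:11)
  expect_equal(cp$stop, 7:12)
  expect_equal(cp$event, c(rep(0L, 5), 1L))
  expect_equal(cp$steps, rep(8000, 6))
})

test_that("invalid months create gaps and the interval bookkeeping balances", {
  co <- list(cohort = data.frame(person_id = "B", entry = 6, exit = 14.5,
                                 event = 0L, stringsAsFactors = FALSE),
             excluded = data.frame(), washout_months = 6)
  valid <- rep(TRUE, 15); valid[c(8, 11)] <- FALSE  # months 7 and 10 invalid
  monthly <- make_monthly("B", seq(7000, by = 100, length.out = 15), valid)
  cp <- build_counting_process(co, monthly)
  # intervals whose preceding month (7 or 10) is invalid are gaps
  expect_false(any(cp$start %in% c(8, 11)))
  expect_equal(sum(cp$stop - cp$start), (14.5 - 6) - 2)
  expect_equal(attr(cp, "n_intervals_gap"), 2)
  # month-mode exposure is the preceding month's mean
  cpm <- build_counting_process(co, monthly, exposure_mode = "month")
  expect_equal(cpm$steps, monthly$mean_steps[cpm$start])  # 0-based lag
})

test_that("a person with no usable months contributes zero rows, logged", {
  co <- list(cohort = data.frame(person_id = "B", entry = 6, exit = 10,
                                 event = 1L, stringsAsFactors = FALSE),
             excluded = data.frame(), washout_months = 6)
  monthly <- make_monthly("B", rep(8000, 11), valid = FALSE)
  cp <- build_counting_process(co, monthly)
  expect_equal(nrow(cp), 0)
  expect_equal(attr(cp, "dropped_no_exposure"), "B")
})

test_that("no information leaks from on/after the event month", {
  cfg <- sim_config(n_participants = 80, seed = 91,
                    hazard_spec = hazard_loglinear(0.8), n_null_phecodes = 0)
  sim <- simulate_study(cfg)
  pe <- map_events_to_phecodes(sim$conditions, sim$map)
  cens <- censoring_date(sim$encounters, sim$conditions)
  mon <- data.frame(person_id = sim$truth$person_id,
                    start_date = sim$truth$start_date)
  co <- build_incident_cohort(pe, mon, cens, "401.1")
  evp <- co$cohort[co$cohort$event == 1, ]
  expect_gt(nrow(evp), 0)  # the fixed seed yields events by construction
  p1 <- evp$person_id[1]
  daily2 <- sim$daily
  sel <- daily2$person_id == p1 &
    daily2$month_index >= floor(evp$exit[1])
  daily2$total_steps[sel] <- daily2$total_steps[sel] * 10 + 5000
  cp_a <- build_counting_process(co, monthly_exposures_all(sim$daily))
  cp_b <- build_counting_process(co, monthly_exposures_all(daily2))
  expect_equal(cp_a[cp_a$person_id == p1, ], cp_b[cp_b$person_id == p1, ])
})

test_that("vectorised monthly exposures agree with the per-person routine", {
  cfg <- sim_config(n_participants = 12, seed = 93)
  co <- gen_cohort(cfg)
  daily <- gen_daily_series(co, cfg)
  all_m <- monthly_exposures_all(daily)
  for (p in co$truth$person_id[c(1, 5, 12)]) {
    d <- daily[daily$person_id == p & daily$total_steps >= 100, ]
    one <- monthly_exposures(d, monitoring_start = min(daily$date[
      daily$person_id == p]))
    got <- all_m[all_m$person_id == p, ]
    rows <- seq_len(nrow(one))
    expect_equal(got$n_valid_days[rows], one$n_valid_days)
    expect_equal(got$mean_steps[rows], one$mean_steps)
    expect_equal(got$running_mean_steps[rows], one$running_mean_steps)
    expect_equal(got$is_valid_month[rows], one$is_valid_month)
  }
})
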