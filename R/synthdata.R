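# Synthetic cohort generator: covariates, daily/minute step streams, and
# EHR-style condition/encounter events with known ground-truth hazard-step
# relationships. Everything is deterministic given the config seed.

#' Hazard specifications for the synthetic event generator
#'
#' The monthly event hazard for a participant is
#' `baseline_monthly_hazard * exp(lp(s))`, where `s` is the participant's
#' true running-average daily step count entering that month. `hazard_null()`
#' makes events independent of steps; `hazard_loglinear()` uses a log-linear
#' effect (constant hazard ratio per 1,000 steps); `hazard_plateau()` is
#' log-linear below a knot and flat above it, emulating risk curves with an
#' inflection around 8,000-9,000 steps/day.
#'
#' @param hr_per_1000 hazard ratio per 1,000 step/day increase (protective
#'   scenarios use values < 1).
#' @param center steps/day at which the hazard multiplier is 1.
#' @param knot steps/day above which the plateau hazard is flat.
#' @return object of class `hazard_spec` with elements `type` and `lp`
#'   (a vectorized function of steps/day returning the log multiplier).
#' @export
hazard_null <- function() {
  structure(list(type = "null", lp = function(s) rep(0, length(s))),
            class = "hazard_spec")
}

#' @rdname hazard_null
#' @export
hazard_loglinear <- function(hr_per_1000 = 0.80, center = 7700) {
  beta <- log(hr_per_1000) / 1000
  structure(list(type = "loglinear", beta_per_step = beta, center = center,
                 hr_per_1000 = hr_per_1000,
                 lp = function(s) beta * (s - center)),
            class = "hazard_spec")
}

#' @rdname hazard_null
#' @export
hazard_plateau <- function(knot = 9000, hr_per_1000 = 0.80, center = 7700) {
  beta <- log(hr_per_1000) / 1000
  structure(list(type = "plateau", beta_per_step = beta, knot = knot,
                 center = center, hr_per_1000 = hr_per_1000,
                 lp = function(s) beta * (pmin(s, knot) - center)),
            class = "hazard_spec")
}

#' Simulation configuration
#'
#' Defaults emulate the published activity-monitoring cohort this pipeline
#' targets: person-level average daily steps log-normal with median 7,731
#' steps/day (IQR ~5,870-9,830), monitoring duration uniform on 0.5-7.5
#' years (median 4.0), mean wear time 14 h/day, and clustered non-wear such
#' that roughly 15% of 30-day months have fewer than 15 valid days.
#'
#' @param n_participants number of participants (>= 1).
#' @param seed integer master seed; every stream derives from it.
#' @param monitoring_years monitoring duration (years) when
#'   `vary_duration = FALSE`; otherwise its midpoint target.
#' @param vary_duration draw per-person durations uniform on 0.5-7.5 years.
#' @param step_level_median median of the person-level mean daily steps.
#' @param step_level_sdlog log-scale SD of person-level mean daily steps.
#' @param step_day_sdlog log-scale SD of day-to-day totals within person.
#' @param wear_hours_mean,wear_hours_sd daily wear hours on worn days.
#' @param frac_nonwear_days marginal fraction of fully non-worn days.
#' @param wear_propensity_precision Beta precision of the per-person-month
#'   wear propensity (smaller = more clustered non-wear).
#' @param hazard_spec a [hazard_null()], [hazard_loglinear()] or
#'   [hazard_plateau()] object for the primary outcome.
#' @param baseline_monthly_hazard baseline event hazard per 30-day month.
#' @param n_null_phecodes number of additional outcomes generated with
#'   step-independent hazards (exercises the phenome-wide screen).
#' @param frac_prevalent,frac_washout fraction of participants given an
#'   outcome code before monitoring start / during the washout (they become
#'   outcome-specific exclusions downstream).
#' @param covariate_missingness named proportions of MCAR missingness per
#'   covariate, or a single proportion applied to all imputable covariates.
#' @param bout_intensity_mix list controlling within-day cadence structure:
#'   `cadence60_mean/sd` (steps/min of slow-walking bouts),
#'   `cadence100_shift` (extra cadence of moderate-vigorous bouts),
#'   `bout_step_frac` (fraction of daily steps accrued in bouts),
#'   `volume_coupling` (correlation strength between person-level step
#'   volume and bout cadence).
#' @param date_shift apply a uniform random 1-365 day shift per participant
#'   to all emitted dates (privacy-transform mimic; must not change any
#'   downstream estimate).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_participants,
                       seed = 1L,
                       monitoring_years = 4,
                       vary_duration = TRUE,
                       step_level_median = 7731,
                       step_level_sdlog = 0.38,
                       step_day_sdlog = 0.35,
                       wear_hours_mean = 14,
                       wear_hours_sd = 2,
                       frac_nonwear_days = 0.20,
                       wear_propensity_precision = 1.5,
                       hazard_spec = hazard_null(),
                       baseline_monthly_hazard = 0.0025,
                       n_null_phecodes = 8,
                       frac_prevalent = 0.02,
                       frac_washout = 0.01,
                       covariate_missingness = NULL,
                       bout_intensity_mix = list(cadence60_mean = 85,
                                                 cadence60_sd = 8,
                                                 cadence100_shift = 25,
                                                 bout_step_frac = 0.45,
                                                 volume_coupling = 0.65),
                       date_shift = FALSE) {
  if (n_participants < 1) stopf("n_participants must be >= 1")
  if (!inherits(hazard_spec, "hazard_spec")) stopf("invalid hazard_spec")
  default_miss <- c(race = 0.054, sex = 0.014, ethnicity = 0.013,
                    education = 0.004, smoking = 0.018, alcohol = 0.005,
                    bmi = 0.438, sbp = 0.10)
  if (is.null(covariate_missingness)) {
    covariate_missingness <- default_miss
  } else if (length(covariate_missingness) == 1 &&
             is.null(names(covariate_missingness))) {
    covariate_missingness <- stats::setNames(
      rep(covariate_missingness, length(default_miss)), names(default_miss))
  }
  if (any(covariate_missingness < 0 | covariate_missingness > 1)) {
    stopf("covariate_missingness must be within [0, 1]")
  }
  if (frac_nonwear_days < 0 || frac_nonwear_days >= 1) {
    stopf("frac_nonwear_days must be in [0, 1)")
  }
  structure(list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    monitoring_years = monitoring_years, vary_duration = vary_duration,
    step_level_median = step_level_median,
    step_level_sdlog = step_level_sdlog, step_day_sdlog = step_day_sdlog,
    wear_hours_mean = wear_hours_mean, wear_hours_sd = wear_hours_sd,
    frac_nonwear_days = frac_nonwear_days,
    wear_propensity_precision = wear_propensity_precision,
    hazard_spec = hazard_spec,
    baseline_monthly_hazard = baseline_monthly_hazard,
    n_null_phecodes = as.integer(n_null_phecodes),
    frac_prevalent = frac_prevalent, frac_washout = frac_washout,
    covariate_missingness = covariate_missingness,
    bout_intensity_mix = bout_intensity_mix,
    date_shift = date_shift), class = "sim_config")
}

#' Expected fraction of invalid months under a simulation config
#'
#' Closed-form (numerical integration) expectation of the fraction of
#' 30-day months with fewer than `min_valid_days` valid days, given the
#' config's Beta wear-propensity and wear-hour distribution. Used to verify
#' that the pipeline's measured excluded-month fraction matches the
#' generator's injected non-wear process.
#'
#' @param config a [sim_config()].
#' @param min_valid_days validity threshold (default 15).
#' @return expected invalid-month proportion.
#' @export
expected_invalid_month_rate <- function(config, min_valid_days = 15) {
  mu <- 1 - config$frac_nonwear_days
  phi <- config$wear_propensity_precision
  p10 <- stats::pnorm((config$wear_hours_mean - 9.5) / config$wear_hours_sd)
  stats::integrate(function(q) {
    stats::dbeta(q, mu * phi, (1 - mu) * phi) *
      stats::pbinom(min_valid_days - 1, 30, q * p10)
  }, 0, 1)$value
}

#' Generate participant covariates and ground-truth person parameters
#'
#' @param config a [sim_config()].
#' @return list: `covariates` (with MCAR missingness injected),
#'   `covariates_complete` (pre-missingness copy), and `truth`
#'   (person-level step level, monitoring duration, start date).
#' @export
gen_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_participants
  with_seed(child_seed(config$seed, "cohort"), {
    id <- sprintf("P%05d", seq_len(n))
    age <- pmin(pmax(stats::rnorm(n, 55, 19), 18), 90)
    sex <- sample(c("Female", "Male"), n, TRUE, prob = c(0.735, 0.265))
    race <- sample(c("Black", "Other", "White"), n, TRUE,
                   prob = c(0.059, 0.054, 0.887))
    ethnicity <- sample(c("Hispanic or Latino", "Not Hispanic or Latino"),
                        n, TRUE, prob = c(0.063, 0.937))
    education <- sample(c("College degree", "Some college", "No college"),
                        n, TRUE, prob = c(0.717, 0.224, 0.059))
    smoking <- sample(c(">100 cigarettes", "<100 cigarettes"), n, TRUE,
                      prob = c(0.326, 0.674))
    alcohol <- sample(c("Alcohol participant", "Not an alcohol participant"),
                      n, TRUE, prob = c(0.973, 0.027))
    bmi <- stats::rlnorm(n, log(28.1), 0.224)
    sbp <- stats::rnorm(n, 125, 15)
    cad <- stats::rbinom(n, 1, 0.028)
    cancer <- stats::rbinom(n, 1, 0.237)
    step_level <- stats::rlnorm(n, log(config$step_level_median),
                                config$step_level_sdlog)
    dur <- if (config$vary_duration) stats::runif(n, 0.5, 7.5) else
      rep(config$monitoring_years, n)
    start <- as.Date("2018-01-01") + sample(0:364, n, TRUE)
    cov <- data.frame(person_id = id, age = age, sex = sex, race = race,
                      ethnicity = ethnicity, education = education,
                      smoking = smoking, alcohol = alcohol, bmi = bmi,
                      sbp = sbp, cad = cad, cancer = cancer,
                      stringsAsFactors = FALSE)
    complete <- cov
    for (v in names(config$covariate_missingness)) {
      if (!v %in% names(cov)) next
      miss <- stats::runif(n) < config$covariate_missingness[[v]]
      cov[[v]][miss] <- NA
    }
    # drawn last so the privacy shift perturbs no other stream
    if (config$date_shift) start <- start + sample(1:365, n, TRUE)
    truth <- data.frame(person_id = id, step_level = step_level,
                        duration_years = dur,
                        n_days = pmax(30L, as.integer(round(dur * 365))),
                        start_date = start, stringsAsFactors = FALSE)
    list(covariates = cov, covariates_complete = complete, truth = truth)
  })
}

#' Generate daily step summaries for a whole cohort (fast path)
#'
#' Draws worn/non-worn days from a clustered per-person-month wear
#' propensity, wear hours, daily totals, and cadence-bout summary metrics,
#' without materialising minute streams. The returned table has the same
#' schema the wearables module produces from minute data, so all downstream
#' stages run identically on either path.
#'
#' @param cohort result of [gen_cohort()].
#' @param config a [sim_config()].
#' @return daily-summary data.frame with `person_id`, `date`, `day_index`,
#'   `month_index`, `total_steps`, `wear_hours`, bout columns, `is_valid`,
#'   `worn`.
#' @export
gen_daily_series <- function(cohort, config) {
  tr <- cohort$truth
  mix <- config$bout_intensity_mix
  with_seed(child_seed(config$seed, "daily"), {
    nd <- tr$n_days
    n_tot <- sum(nd)
    pid <- rep(tr$person_id, nd)
    day_index <- sequence(nd) - 1L
    month_index <- day_index %/% 30L
    # per person-month wear propensity (clustered non-wear)
    mu <- 1 - config$frac_nonwear_days
    phi <- config$wear_propensity_precision
    nmonth <- (nd - 1L) %/% 30L + 1L
    q <- stats::rbeta(sum(nmonth), mu * phi, (1 - mu) * phi)
    month_of_row <- month_index + rep(cumsum(c(0L, nmonth[-length(nmonth)])),
                                      nd) + 1L
    worn <- stats::runif(n_tot) < q[month_of_row]
    iw <- which(worn)
    nw <- length(iw)
    wear_hours <- integer(n_tot)
    wear_hours[iw] <- pmin.int(pmax.int(as.integer(round(
      stats::rnorm(nw, config$wear_hours_mean, config$wear_hours_sd))),
      1L), 18L)
    level_w <- rep(tr$step_level, nd)[iw]
    total <- numeric(n_tot)
    sdd <- config$step_day_sdlog
    total[iw] <- round(stats::rlnorm(nw, log(level_w) - sdd^2 / 2, sdd))
    # person-level cadence structure (bout metrics on worn days only);
    # cadence is coupled to step volume so that faster walkers also walk
    # more, as observed in free-living cohorts
    rho <- mix$volume_coupling %||% 0.65
    zlev <- as.numeric(scale(log(tr$step_level)))
    if (any(!is.finite(zlev))) zlev <- rep(0, nrow(tr))
    c60 <- pmin(pmax(mix$cadence60_mean + mix$cadence60_sd *
                       (rho * zlev +
                          sqrt(1 - rho^2) * stats::rnorm(nrow(tr))),
                     62), 130)
    c100 <- pmax(c60 + stats::rnorm(nrow(tr), mix$cadence100_shift, 5), 102)
    bf <- stats::rbeta(nrow(tr), 10 * mix$bout_step_frac,
                       10 * (1 - mix$bout_step_frac))
    f100 <- stats::rbeta(nrow(tr), 2.8, 5.2)
    person_w <- rep(seq_len(nrow(tr)), nd)[iw]
    bfd <- bf[person_w] * exp(stats::rnorm(nw, 0, 0.2))
    bs60w <- pmin.int(bfd, 0.9) * total[iw]
    bs100w <- pmin.int(f100[person_w] * exp(stats::rnorm(nw, 0, 0.25)),
                       0.95) * bs60w
    n60w <- pmax.int(2, round(bs60w / c60[person_w]))
    n60w[bs60w <= 0] <- 0
    n100w <- round(bs100w / c100[person_w])
    # a 100-threshold bout needs >= 2 minutes; below that it does not exist
    bs100w[n100w < 2] <- 0
    n100w[n100w < 2] <- 0
    bs60 <- bs100 <- n60 <- n100 <- numeric(n_tot)
    bs60[iw] <- round(bs60w); bs100[iw] <- round(bs100w)
    n60[iw] <- n60w; n100[iw] <- n100w
    is_valid <- worn & wear_hours >= 10L & total >= 100
    data.frame(person_id = pid,
               date = rep(tr$start_date, nd) + day_index,
               day_index = day_index, month_index = month_index,
               total_steps = total, wear_hours = wear_hours,
               n_bout_minutes_60 = n60, bout_steps_60 = bs60,
               n_bout_minutes_100 = n100, bout_steps_100 = bs100,
               is_valid = is_valid, worn = worn,
               stringsAsFactors = FALSE)
  })
}

#' Generate a minute-level step stream for one participant
#'
#' Constructive allocator: per worn day it picks wear hours, lays down
#' cadence bouts (runs of >= 2 minutes at >= 60 steps/min, a subset at
#' >= 100), and spreads the remaining steps over background minutes below
#' 60 steps/min, so the day total matches the drawn target. Non-worn days
#' are all zeros. The realised per-day totals are attached as attribute
#' `daily_truth` (the bookkeeping oracle for `summarize_days`).
#'
#' @param participant one row of `gen_cohort()$truth` (or a list with
#'   `person_id`, `step_level`, `n_days`, `start_date`).
#' @param config a [sim_config()].
#' @param n_days optional override of the number of monitored days.
#' @return data.frame `participant_id`, `timestamp` (POSIXct UTC, one row
#'   per minute slot of each monitored day), `steps`.
#' @export
gen_minute_stream <- function(participant, config, n_days = NULL) {
  p <- as.list(participant)
  nd <- as.integer(n_days %||% p$n_days)
  if (nd < 1) stopf("n_days must be >= 1")
  mix <- config$bout_intensity_mix
  sdd <- config$step_day_sdlog
  with_seed(child_seed(config$seed, paste0("minute-", p$person_id)), {
    mat <- matrix(0, nrow = 1440, ncol = nd)
    worn <- stats::runif(nd) >= config$frac_nonwear_days
    totals <- numeric(nd)
    for (d in which(worn)) {
      H <- min(max(round(stats::rnorm(1, config$wear_hours_mean,
                                      config$wear_hours_sd)), 1), 18)
      st <- sample(5:min(9, 23 - H + 1), 1)
      hours <- st:(st + H - 1)
      wear_min <- as.vector(outer(0:59, hours * 60, `+`)) + 1L
      target <- round(stats::rlnorm(1, log(p$step_level) - sdd^2 / 2, sdd))
      target <- max(target, H * 2)  # enough room for one step per slot
      day <- numeric(1440)
      # bouts
      bout_budget <- mix$bout_step_frac * target
      free <- wear_min
      placed <- 0
      while (placed < bout_budget && length(free) > 12) {
        len <- sample(2:8, 1)
        cad <- min(max(stats::rnorm(1, mix$cadence60_mean,
                                    mix$cadence60_sd), 62), 130)
        if (stats::runif(1) < 0.3) cad <- cad + mix$cadence100_shift
        anchor <- sample(seq_along(free), 1)
        pos <- free[anchor] + 0:(len - 1)
        pos <- pos[pos %in% free]
        if (length(pos) < 2) next
        day[pos] <- round(cad)
        placed <- placed + sum(day[pos])
        free <- setdiff(free, pos)
      }
      rem <- target - sum(day)
      if (rem > 0 && length(free) > 0) {
        n_bg <- min(length(free), max(ceiling(rem / 45), H))
        bg <- sample(free, n_bg)
        base <- rem %/% n_bg
        if (base > 59) { # cap background cadence; spill into extra bouts
          day[bg] <- 59
          spill <- rem - 59 * n_bg
          extra <- setdiff(free, bg)
          if (length(extra) > 0 && spill > 0) {
            k <- min(length(extra), ceiling(spill / 110))
            em <- sample(extra, k)
            day[em] <- day[em] + ceiling(spill / k)
          }
        } else {
          day[bg] <- base
          left <- rem - base * n_bg
          if (left > 0) day[bg[seq_len(left)]] <- day[bg[seq_len(left)]] + 1
        }
      }
      # guarantee every wear hour registers (wear-time bookkeeping)
      for (h in hours) {
        sl <- (h * 60):(h * 60 + 59) + 1L
        if (all(day[sl] == 0)) day[sl[30]] <- 1
      }
      mat[, d] <- day
      totals[d] <- sum(day)
    }
    dates <- rep(p$start_date + (seq_len(nd) - 1L), each = 1440)
    ts <- as.POSIXct(dates, tz = "UTC") + rep(0:1439 * 60, nd)
    out <- data.frame(participant_id = p$person_id, timestamp = ts,
                      steps = as.vector(mat), stringsAsFactors = FALSE)
    attr(out, "daily_truth") <- data.frame(
      date = p$start_date + (seq_len(nd) - 1L), total_steps = totals,
      worn = worn)
    out
  })
}

# True monthly running-average exposure from worn-day totals (ground truth;
# the analysis recomputes its own version from valid days only).
.true_monthly_running <- function(daily) {
  iw <- which(daily$worn)
  pid_levels <- unique(daily$person_id)
  pi <- match(daily$person_id[iw], pid_levels)
  key <- (pi - 1) * 1e6 + daily$month_index[iw]
  agg <- rowsum(cbind(s = daily$total_steps[iw], n = 1), key)
  akey <- as.numeric(rownames(agg))
  ap <- as.integer(akey %/% 1e6) + 1L
  am <- as.integer(akey %% 1e6)
  # rowsum output is key-sorted, i.e. grouped by person with months ascending
  new_p <- c(TRUE, ap[-1] != ap[-length(ap)])
  cs <- cumsum(agg[, "s"]); cn <- cumsum(agg[, "n"])
  base_s <- cumsum(c(0, agg[-nrow(agg), "s"]))[new_p][cumsum(new_p)]
  base_n <- cumsum(c(0, agg[-nrow(agg), "n"]))[new_p][cumsum(new_p)]
  data.frame(person_id = pid_levels[ap], month_index = am,
             true_running_mean = (cs - base_s) / (cn - base_n),
             stringsAsFactors = FALSE)
}

# Piecewise-constant-hazard event sampler by inverse-transform on the
# cumulative hazard. Hazard in month m uses the true running mean through
# month m-1 (month 0 uses the person's true step level).
.sample_event_times <- function(truth, true_monthly, hazard_spec, baseline) {
  split_tm <- split(true_monthly, true_monthly$person_id)
  n <- nrow(truth)
  ev_month <- rep(NA_real_, n)
  u <- stats::rexp(n)
  for (i in seq_len(n)) {
    pid <- truth$person_id[i]
    M <- (truth$n_days[i] - 1L) %/% 30L + 1L
    tm <- split_tm[[pid]]
    s <- rep(truth$step_level[i], M)
    if (!is.null(tm)) {
      run <- rep(NA_real_, M)
      run[tm$month_index + 1L] <- tm$true_running_mean
      # hazard in month m driven by exposure through month m-1
      filled <- run
      if (is.na(filled[1])) filled[1] <- truth$step_level[i]
      for (m in seq_len(M)[-1]) {
        if (is.na(filled[m])) filled[m] <- filled[m - 1]
      }
      if (M >= 2) s[2:M] <- filled[1:(M - 1)]
      s[1] <- truth$step_level[i]
    }
    h <- baseline * exp(hazard_spec$lp(s))
    if (any(!is.finite(h))) stopf("hazard spec produced non-finite rates")
    H <- cumsum(h)
    m <- which(H >= u[i])[1]
    if (!is.na(m)) {
      prev <- if (m == 1) 0 else H[m - 1]
      ev_month[i] <- (m - 1) + (u[i] - prev) / h[m]
    }
  }
  ev_month
}

#' Generate condition and encounter event tables with known ground truth
#'
#' Event times for the primary outcome are drawn from a piecewise-constant
#' (per 30-day month) hazard `baseline * exp(lp(s))` where `s` is the true
#' running-average daily step count entering the month. Additional
#' step-independent outcomes, prevalent/washout occurrences, and unmapped
#' noise codes are emitted so that mapping, exclusion, and censoring logic
#' is exercised. Encounters (measurement/lab/procedure/condition domains)
#' are emitted through each participant's monitoring end, which therefore
#' defines the censoring date.
#'
#' @param cohort result of [gen_cohort()].
#' @param daily result of [gen_daily_series()] (supplies true exposures).
#' @param config a [sim_config()].
#' @return list: `conditions` (person_id, date, code, vocabulary),
#'   `encounters` (person_id, date, domain), `map` (phecode map fixture),
#'   `ground_truth` (true event months per outcome, hazard spec, true
#'   HR(75th vs 25th percentile)).
#' @export
gen_outcome_events <- function(cohort, daily, config) {
  tr <- cohort$truth
  map <- gen_phecode_map_fixture(config$n_null_phecodes)
  true_monthly <- .true_monthly_running(daily)
  outcomes <- list(list(name = "hypertension", phecode = "401.1",
                        codes = data.frame(
                          vocabulary = c("ICD10CM", "ICD9CM"),
                          code = c("I10", "401.1")),
                        spec = config$hazard_spec,
                        baseline = config$baseline_monthly_hazard),
                   list(name = "sleep_apnea", phecode = "327.3",
                        codes = data.frame(
                          vocabulary = c("ICD10CM", "ICD10CM"),
                          code = c("G47.30", "G47.33")),
                        spec = hazard_null(),
                        baseline = config$baseline_monthly_hazard))
  with_seed(child_seed(config$seed, "events"), {
    if (config$n_null_phecodes > 0) {
      for (k in seq_len(config$n_null_phecodes)) {
        outcomes[[length(outcomes) + 1]] <- list(
          name = sprintf("null_%02d", k),
          phecode = sprintf("900.%02d", k),
          codes = data.frame(vocabulary = "ICD10CM",
                             code = sprintf("N%02d.9", k)),
          spec = hazard_null(),
          baseline = stats::runif(1, 5e-4, 3e-3))
      }
    }
    cond <- list(); gt_events <- list()
    for (oc in outcomes) {
      ev <- .sample_event_times(tr, true_monthly, oc$spec, oc$baseline)
      has <- which(!is.na(ev))
      if (length(has) > 0) {
        ci <- sample(nrow(oc$codes), length(has), TRUE)
        cond[[length(cond) + 1]] <- data.frame(
          person_id = tr$person_id[has],
          date = tr$start_date[has] + round(ev[has] * 30),
          code = oc$codes$code[ci], vocabulary = oc$codes$vocabulary[ci],
          stringsAsFactors = FALSE)
      }
      # prevalent and washout occurrences (outcome-specific exclusions)
      prev <- which(stats::runif(nrow(tr)) < config$frac_prevalent)
      if (length(prev) > 0) {
        cond[[length(cond) + 1]] <- data.frame(
          person_id = tr$person_id[prev],
          date = tr$start_date[prev] - round(stats::runif(length(prev), 30, 720)),
          code = oc$codes$code[1], vocabulary = oc$codes$vocabulary[1],
          stringsAsFactors = FALSE)
      }
      wash <- which(stats::runif(nrow(tr)) < config$frac_washout)
      if (length(wash) > 0) {
        cond[[length(cond) + 1]] <- data.frame(
          person_id = tr$person_id[wash],
          date = tr$start_date[wash] + round(stats::runif(length(wash), 0, 179)),
          code = oc$codes$code[1], vocabulary = oc$codes$vocabulary[1],
          stringsAsFactors = FALSE)
      }
      gt_events[[oc$name]] <- data.frame(person_id = tr$person_id,
                                         event_month = ev,
                                         stringsAsFactors = FALSE)
    }
    # unmapped noise codes (dropped and logged by the mapper)
    nz <- which(stats::runif(nrow(tr)) < 0.05)
    if (length(nz) > 0) {
      cond[[length(cond) + 1]] <- data.frame(
        person_id = tr$person_id[nz],
        date = tr$start_date[nz] + round(stats::runif(length(nz), 0, 600)),
        code = "Z00.0", vocabulary = "ICD10CM", stringsAsFactors = FALSE)
    }
    conditions <- if (length(cond) > 0) do.call(rbind, cond) else
      data.frame(person_id = character(), date = as.Date(character()),
                 code = character(), vocabulary = character(),
                 stringsAsFactors = FALSE)
    conditions <- conditions[order(conditions$person_id, conditions$date), ,
                             drop = FALSE]
    rownames(conditions) <- NULL
    # encounters: enrollment, ~6-monthly visits, final at monitoring end
    enc <- lapply(seq_len(nrow(tr)), function(i) {
      nd <- tr$n_days[i]
      mid <- if (nd > 240) seq(180, nd - 60, by = 180) else numeric(0)
      if (length(mid) > 0) mid <- mid + round(stats::runif(length(mid), -30, 30))
      days <- unique(c(0, mid[mid > 0 & mid < nd], nd - 1L))
      data.frame(person_id = tr$person_id[i], date = tr$start_date[i] + days,
                 domain = sample(c("measurement", "lab", "procedure",
                                   "condition"), length(days), TRUE),
                 stringsAsFactors = FALSE)
    })
    encounters <- do.call(rbind, enc)
    # true contrast implied by the hazard spec and the person-level
    # exposure distribution
    q <- stats::quantile(tr$step_level, c(0.25, 0.75))
    hs <- config$hazard_spec
    true_hr <- exp(hs$lp(q[[2]]) - hs$lp(q[[1]]))
    list(conditions = conditions, encounters = encounters, map = map,
         ground_truth = list(
           events = gt_events,
           hazard_spec = config$hazard_spec,
           true_log_hr_per_1000 = if (!is.null(hs$beta_per_step))
             hs$beta_per_step * 1000 else 0,
           true_hr_75_vs_25 = true_hr,
           s25 = q[[1]], s75 = q[[2]]))
  })
}

#' Bundled ICD-to-phecode map fixture
#'
#' Small many-to-one map covering every ICD code the generator emits, with
#' combination flags for phecode pairs analysed as one condition
#' (diabetes-with-manifestation folded into diabetes; obstructive sleep
#' apnea folded into sleep apnea).
#'
#' @param n_null number of synthetic null-condition codes to include.
#' @return data.frame `vocabulary`, `code`, `phecode`, `phecode_label`,
#'   `combine_to` (NA or the phecode this one is analysed under).
#' @export
gen_phecode_map_fixture <- function(n_null = 8) {
  base <- data.frame(
    vocabulary = c("ICD10CM", "ICD9CM", "ICD10CM", "ICD9CM", "ICD10CM",
                   "ICD10CM", "ICD10CM", "ICD10CM", "ICD9CM", "ICD10CM",
                   "ICD10CM", "ICD10CM", "ICD10CM"),
    code = c("I10", "401.1", "E11.9", "250.00", "E11.40",
             "G47.30", "G47.33", "K21.9", "530.81", "F33.1",
             "E66.9", "G56.00", "L57.0"),
    phecode = c("401.1", "401.1", "250.2", "250.2", "250.24",
                "327.3", "327.23", "530.11", "530.11", "296.22",
                "278.1", "351.2", "702.1"),
    phecode_label = c("Essential hypertension", "Essential hypertension",
                      "Type 2 diabetes", "Type 2 diabetes",
                      "T2D with neurological manifestations",
                      "Sleep apnea", "Obstructive sleep apnea",
                      "GERD", "GERD", "Major depressive disorder",
                      "Obesity", "Carpal tunnel syndrome",
                      "Actinic keratosis"),
    combine_to = c(NA, NA, NA, NA, "250.2", NA, "327.3", NA, NA, NA,
                   NA, NA, NA),
    stringsAsFactors = FALSE)
  if (n_null > 0) {
    nulls <- data.frame(
      vocabulary = "ICD10CM", code = sprintf("N%02d.9", seq_len(n_null)),
      phecode = sprintf("900.%02d", seq_len(n_null)),
      phecode_label = sprintf("Synthetic null condition %d", seq_len(n_null)),
      combine_to = NA_character_, stringsAsFactors = FALSE)
    base <- rbind(base, nulls)
  }
  base
}

#' Simulate a complete study dataset
#'
#' Runs [gen_cohort()], [gen_daily_series()] and [gen_outcome_events()]
#' under one master seed and returns every table the downstream pipeline
#' ingests, together with the ground truth.
#'
#' @param config a [sim_config()].
#' @return list with `config`, `covariates`, `covariates_complete`,
#'   `daily`, `conditions`, `encounters`, `map`, `ground_truth`, `truth`.
#' @export
simulate_study <- function(config) {
  cohort <- gen_cohort(config)
  daily <- gen_daily_series(cohort, config)
  ev <- gen_outcome_events(cohort, daily, config)
  list(config = config, covariates = cohort$covariates,
       covariates_complete = cohort$covariates_complete,
       truth = cohort$truth, daily = daily,
       conditions = ev$conditions, encounters = ev$encounters,
       map = ev$map, ground_truth = ev$ground_truth)
}

#' Write a simulated study to disk as plain-text tables
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_sim_data <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(covariates = file.path(dir, "covariates.csv"),
             daily = file.path(dir, "daily_steps.csv"),
             conditions = file.path(dir, "conditions.csv"),
             encounters = file.path(dir, "encounters.csv"),
             map = file.path(dir, "phecode_map.csv"),
             ground_truth = file.path(dir, "ground_truth.json"))
  utils::write.csv(sim$covariates, paths["covariates"], row.names = FALSE)
  utils::write.csv(sim$daily, paths["daily"], row.names = FALSE)
  utils::write.csv(sim$conditions, paths["conditions"], row.names = FALSE)
  utils::write.csv(sim$encounters, paths["encounters"], row.names = FALSE)
  utils::write.csv(sim$map, paths["map"], row.names = FALSE)
  gt <- sim$ground_truth
  gt$hazard_spec <- gt$hazard_spec[c("type", "beta_per_step", "knot",
                                     "center")[c("type", "beta_per_step",
                                                 "knot", "center") %in%
                                                 names(gt$hazard_spec)]]
  jsonlite::write_json(gt, paths["ground_truth"], auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(paths)
}
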