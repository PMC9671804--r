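# End-to-end orchestration: simulate or ingest -> wearable processing ->
# phenome screen -> time-varying Cox suite -> report files.

#' Baseline step-count windows per person
#'
#' Mean valid-day steps over the first `months` 30-day months of monitoring
#' (reverse-causation adjustment covariates).
#'
#' @param daily cohort daily-summary data.frame.
#' @param months window lengths (default 3 and 6).
#' @return data.frame `person_id` plus one `baseline_steps_<m>mo` column per
#'   window.
#' @export
baseline_windows <- function(daily, months = c(3, 6)) {
  iv <- which(daily$is_valid & daily$total_steps >= 100)
  pid <- unique(daily$person_id)
  pi <- match(daily$person_id[iv], pid)
  dn <- as.numeric(daily$date[iv])
  start <- rep(NA_real_, length(pid))
  mn_by_group <- vapply(split(dn, pi), min, numeric(1))
  start[as.integer(names(mn_by_group))] <- mn_by_group
  off <- dn - start[pi]
  out <- data.frame(person_id = pid, stringsAsFactors = FALSE)
  for (mo in months) {
    sel <- off < mo * 30
    agg <- rowsum(cbind(s = daily$total_steps[iv][sel], n = 1), pi[sel])
    col <- rep(NA_real_, length(pid))
    col[as.integer(rownames(agg))] <- agg[, "s"] / agg[, "n"]
    out[[sprintf("baseline_steps_%dmo", mo)]] <- col
  }
  out
}

#' Step trajectories by window and event status
#'
#' Mean valid-day steps over the 0-3, 3-6, 6-12 and 12-24 month windows,
#' summarised separately for persons who did and did not develop the
#' outcome.
#'
#' @param daily cohort daily-summary data.frame.
#' @param cohort incident cohort data.frame (`person_id`, `event`).
#' @return data.frame `window`, `event`, `mean_steps`, `n`.
#' @export
trajectory_table <- function(daily, cohort) {
  wins <- list(c(0, 3), c(3, 6), c(6, 12), c(12, 24))
  v <- daily$is_valid & daily$total_steps >= 100 &
    daily$person_id %in% cohort$person_id
  d <- daily[v, ]
  dn <- as.numeric(as.Date(d$date))
  start <- tapply(dn, d$person_id, min)
  off <- dn - start[d$person_id]
  ev <- cohort$event[match(d$person_id, cohort$person_id)]
  rows <- list()
  for (w in wins) {
    sel <- off >= w[1] * 30 & off < w[2] * 30
    for (e in c(0, 1)) {
      s <- sel & ev == e
      pm <- tapply(d$total_steps[s], d$person_id[s], mean)
      rows[[length(rows) + 1]] <- data.frame(
        window = sprintf("%d-%d months", w[1], w[2]), event = e,
        mean_steps = if (length(pm)) mean(pm) else NA_real_,
        n = length(pm))
    }
  }
  do.call(rbind, rows)
}

#' Descriptive characteristics table with two-group comparisons
#'
#' Median (IQR) with Mann-Whitney U tests for continuous variables and
#' count (percent of group) with chi-squared tests for categorical ones.
#'
#' @param covariates covariate data.frame.
#' @param group logical or 2-level vector aligned with rows (e.g. included
#'   vs excluded).
#' @param continuous,categorical column names to summarise.
#' @return data.frame `variable`, `level`, per-group summaries, `p_value`.
#' @export
descriptive_table <- function(covariates, group,
                              continuous = c("age", "bmi", "sbp"),
                              categorical = c("sex", "race", "ethnicity",
                                              "education", "smoking",
                                              "alcohol", "cad", "cancer")) {
  g <- factor(group)
  if (nlevels(g) > 2) stopf("group must have at most 2 levels")
  lv <- levels(g)
  two <- nlevels(g) == 2 && all(table(g) > 0)
  rows <- list()
  fmt <- function(x) sprintf("%.1f (%.1f-%.1f)", stats::median(x, na.rm = TRUE),
                             stats::quantile(x, 0.25, na.rm = TRUE),
                             stats::quantile(x, 0.75, na.rm = TRUE))
  for (v in intersect(continuous, names(covariates))) {
    x <- covariates[[v]]
    p <- if (two) tryCatch(
      stats::wilcox.test(x ~ g)$p.value, error = function(e) NA_real_)
    else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, level = "",
      group1 = fmt(x[g == lv[1]]),
      group2 = if (two) fmt(x[g == lv[2]]) else "", p_value = p)
  }
  for (v in intersect(categorical, names(covariates))) {
    x <- factor(covariates[[v]])
    p <- if (two) tryCatch(
      suppressWarnings(stats::chisq.test(table(x, g))$p.value),
      error = function(e) NA_real_)
    else NA_real_
    for (l in levels(x)) {
      n1 <- sum(x == l & g == lv[1], na.rm = TRUE)
      n2 <- sum(x == l & g == lv[2], na.rm = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = l,
        group1 = sprintf("%d (%.1f)", n1, 100 * n1 / sum(g == lv[1])),
        group2 = if (two) sprintf("%d (%.1f)", n2,
                                  100 * n2 / sum(g == lv[2])) else "",
        p_value = p)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[3:4] <- paste0("group_", lv[seq_len(2)])[seq_len(2)]
  out
}

#' Recompute percentages from a counts table
#'
#' @param counts data.frame with `count` and `n_group` columns.
#' @return the table with a recomputed `pct` column (100 * count / n_group).
#' @export
recompute_percentages <- function(counts) {
  counts$pct <- 100 * counts$count / counts$n_group
  counts
}

# Per-person pooled bout cadence over valid days (vectorised).
.person_intensity <- function(daily) {
  v <- daily$is_valid & daily$total_steps >= 100
  d <- daily[v, ]
  s60 <- tapply(d$bout_steps_60, d$person_id, sum)
  m60 <- tapply(d$n_bout_minutes_60, d$person_id, sum)
  s100 <- tapply(d$bout_steps_100, d$person_id, sum)
  m100 <- tapply(d$n_bout_minutes_100, d$person_id, sum)
  data.frame(person_id = names(s60),
             mean_bout_cadence_60 = ifelse(m60 > 0, s60 / m60, NA_real_),
             mean_bout_cadence_100 = ifelse(m100 > 0, s100 / m100, NA_real_),
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) a study dataset and runs every stage: monitoring
#' span and valid-day screening, cohort-flow counts, descriptive
#' comparisons, the phenome-wide logistic screen, and per-outcome
#' time-varying Cox analyses (spline knot selection by AIC across the
#' requested model suite, 75th-vs-25th percentile contrasts pooled across
#' imputations with Rubin's rules, chunk tests, HR curves, cumulative
#' incidence, proportional-hazards diagnostics, trajectories), plus
#' falsification outcomes and volume-intensity descriptives.
#'
#' @param config a [sim_config()]; ignored when `sim` is supplied.
#' @param sim a [simulate_study()] result (or equivalently structured list
#'   of ingested tables).
#' @param outcomes named list of target phecode sets (combination sets
#'   analysed as one condition).
#' @param models subset of the [model_suite()] names to fit.
#' @param exposure_mode "running" (running mean of valid days, default) or
#'   "month" (previous month's mean).
#' @param m_imputations imputations for covariate missingness (default 5).
#' @param knot_choices candidate spline knot counts (default 3, 4, 5).
#' @param incidence_steps steps/day values for cumulative-incidence output.
#' @param falsification_phecodes phecodes with no expected step relation;
#'   defaults to the synthetic null phecodes present in the map.
#' @param min_span_months minimum monitoring span for inclusion.
#' @param washout_months washout length (default 6).
#' @return a result bundle (list); see [write_report()] for serialisation.
#' @export
run_full_analysis <- function(config = NULL, sim = NULL,
                              outcomes = list(
                                hypertension = "401.1",
                                sleep_apnea = c("327.3", "327.23")),
                              models = c("M1", "M2"),
                              exposure_mode = c("running", "month"),
                              m_imputations = 5,
                              knot_choices = c(3, 4, 5),
                              incidence_steps = c(6000, 8000, 10000),
                              falsification_phecodes = NULL,
                              min_span_months = 6,
                              washout_months = 6) {
  exposure_mode <- match.arg(exposure_mode)
  if (is.null(sim)) {
    if (is.null(config)) stopf("supply config or sim")
    sim <- simulate_study(config)
  }
  daily <- sim$daily
  stopifnot(all(c("person_id", "date", "total_steps", "wear_hours",
                  "is_valid") %in% names(daily)))
  # ---- cohort flow -------------------------------------------------------
  low <- daily$total_steps < 100
  span <- monitoring_span(daily, min_span_months)
  included <- span$person_id[span$included]
  consort <- data.frame(
    stage = c("participants", "monitoring_span_ok",
              "pct_days_low_steps", "person_days_valid"),
    value = c(length(unique(daily$person_id)), length(included),
              100 * mean(low),
              sum(daily$is_valid & !low)))
  di <- daily[daily$person_id %in% included, ]
  covariates <- sim$covariates[sim$covariates$person_id %in%
                                 unique(daily$person_id), ]
  # ---- descriptives: included vs excluded --------------------------------
  grp <- ifelse(covariates$person_id %in% included, "included", "excluded")
  descr <- descriptive_table(covariates, grp)
  # ---- exposures ---------------------------------------------------------
  pms <- person_mean_steps(di)
  monthly <- monthly_exposures_all(di)
  pct_months_excluded <- 100 * mean(!monthly$is_valid_month)
  monitoring <- data.frame(person_id = sim$truth$person_id,
                           start_date = sim$truth$start_date,
                           stringsAsFactors = FALSE)
  monitoring <- monitoring[monitoring$person_id %in% included, ]
  # ---- phenotypes --------------------------------------------------------
  pe <- map_events_to_phecodes(sim$conditions, sim$map)
  cens <- censoring_date(sim$encounters, sim$conditions)
  # ---- phenome-wide screen ----------------------------------------------
  phew <- run_phewas(pms, covariates, pe, monitoring, cens,
                     washout_months = washout_months)
  # ---- imputation --------------------------------------------------------
  cov_incl <- covariates[covariates$person_id %in% included, ]
  bw <- baseline_windows(di)
  imp <- pmm_impute(cov_incl, m = m_imputations,
                    seed = (sim$config$seed %||% 1) + 17L)
  registry <- model_suite()
  models <- intersect(models, names(registry))
  inten <- .person_intensity(di)
  # ---- per-outcome Cox suite --------------------------------------------
  cohorts <- list(); contrasts <- list(); hr_curves <- list()
  incidence <- list(); trajectories <- list(); ph_tables <- list()
  chunk_tests <- list(); intensity_models <- list()
  for (oc in names(outcomes)) {
    co <- build_incident_cohort(pe, monitoring, cens, outcomes[[oc]],
                                washout_months)
    cohorts[[oc]] <- co
    if (sum(co$cohort$event) < 5) next
    cp0 <- build_counting_process(co, monthly, covariates = NULL,
                                  exposure_mode = exposure_mode)
    pms_oc <- pms$mean_steps[pms$person_id %in% co$cohort$person_id]
    ref <- stats::median(pms_oc)
    # knot choice: total AIC across imputations on the first model
    base_cov <- registry[[models[1]]]
    attach_cov <- function(cp, imdat) {
      cdat <- merge(merge(imdat, bw, by = "person_id", all.x = TRUE),
                    inten, by = "person_id", all.x = TRUE)
      hit <- match(cp$person_id, cdat$person_id)
      cbind(cp, cdat[hit, setdiff(names(cdat), "person_id"),
                     drop = FALSE])
    }
    aic_tot <- sapply(knot_choices, function(k) {
      sum(vapply(imp$imputations, function(imdat) {
        tryCatch(fit_cox_tv(attach_cov(cp0, imdat), knots = k,
                            covariates = base_cov)$aic,
                 error = function(e) Inf)
      }, numeric(1)))
    })
    if (all(!is.finite(aic_tot))) next
    k_sel <- knot_choices[order(aic_tot, knot_choices)][1]
    for (mdl in models) {
      cvs <- setdiff(registry[[mdl]], "wear")
      use_wear <- "wear" %in% registry[[mdl]]
      fits <- tryCatch(lapply(imp$imputations, function(imdat) {
        fit_cox_tv(attach_cov(cp0, imdat), knots = k_sel,
                   covariates = c(cvs, if (use_wear) "wear"))
      }), error = function(e) NULL)
      if (is.null(fits)) next  # e.g. a covariate constant in a small cohort
      ctrs <- lapply(fits, hr_contrast, person_steps = pms_oc)
      pooled <- rubin_pool(vapply(ctrs, `[[`, numeric(1), "log_hr"),
                           vapply(ctrs, `[[`, numeric(1), "se")^2)
      contrasts[[paste(oc, mdl)]] <- data.frame(
        outcome = oc, model = mdl, n = length(unique(cp0$person_id)),
        n_events = sum(cp0$event), knots = k_sel,
        s25 = ctrs[[1]]$s25, s75 = ctrs[[1]]$s75,
        hr = exp(pooled$q_bar), ci_low = exp(pooled$ci_low),
        ci_high = exp(pooled$ci_high), p_value = pooled$p_value)
      p_overall <- stats::median(vapply(fits, function(f)
        wald_chunk_test(f, "exposure")$p_value, numeric(1)))
      p_nonlin <- stats::median(vapply(fits, function(f)
        wald_chunk_test(f, "nonlinear")$p_value, numeric(1)))
      chunk_tests[[paste(oc, mdl)]] <- data.frame(
        outcome = oc, model = mdl, p_overall = p_overall,
        p_nonlinear = p_nonlin)
      if (mdl == models[1]) {
        f1 <- fits[[1]]
        grid <- seq(stats::quantile(pms_oc, 0.05),
                    stats::quantile(pms_oc, 0.95), length.out = 25)
        hc <- hr_curve(f1, grid, ref)
        hc$outcome <- oc
        hr_curves[[oc]] <- hc
        max_m <- max(cp0$stop)
        yrs <- c(3, 5, 7)
        yrs <- yrs[yrs * 365.25 / 30 <= max_m]
        if (length(yrs) > 0) {
          ci <- tryCatch(cumulative_incidence(f1, incidence_steps,
                                              years = yrs),
                         error = function(e) NULL)
          if (!is.null(ci)) {
            ci$outcome <- oc
            incidence[[oc]] <- ci
          }
        }
        # degenerate small-sample fits (infinite coefficients) make the
        # Schoenfeld score test singular; report nothing in that case
        pht <- tryCatch(ph_diagnostics(f1), error = function(e) NULL)
        if (!is.null(pht)) {
          pht$outcome <- oc
          ph_tables[[oc]] <- pht
        }
        # intensity-adjusted variant: bout cadence as a second spline
        im_cp <- attach_cov(cp0, imp$imputations[[1]])
        if (sum(!is.na(im_cp$mean_bout_cadence_60)) > 100) {
          fi <- tryCatch(
            fit_cox_tv(im_cp, knots = k_sel, covariates = base_cov,
                       intensity_col = "mean_bout_cadence_60"),
            error = function(e) NULL)
          if (!is.null(fi)) {
            intensity_models[[oc]] <- data.frame(
              outcome = oc,
              p_steps = wald_chunk_test(fi, "exposure")$p_value,
              p_intensity = wald_chunk_test(fi, "intensity")$p_value)
          }
        }
      }
    }
    tt <- trajectory_table(di, co$cohort)
    tt$outcome <- oc
    trajectories[[oc]] <- tt
  }
  # ---- falsification -----------------------------------------------------
  if (is.null(falsification_phecodes)) {
    falsification_phecodes <- grep("^900\\.", unique(pe$phecode),
                                   value = TRUE)[1:2]
    falsification_phecodes <-
      falsification_phecodes[!is.na(falsification_phecodes)]
  }
  fals <- list()
  for (pc in falsification_phecodes) {
    co <- build_incident_cohort(pe, monitoring, cens, pc, washout_months)
    if (sum(co$cohort$event) < 5) next
    cp <- build_counting_process(co, monthly, covariates = NULL,
                                 exposure_mode = exposure_mode)
    hit <- match(cp$person_id, imp$imputations[[1]]$person_id)
    cp <- cbind(cp, imp$imputations[[1]][hit, c("age", "sex", "race")])
    ft <- tryCatch(fit_cox_tv(cp, knots = 3,
                              covariates = c("age", "sex", "race")),
                   error = function(e) NULL)
    if (!is.null(ft)) {
      fals[[pc]] <- data.frame(
        phecode = pc, n_events = sum(cp$event),
        p_overall = wald_chunk_test(ft, "exposure")$p_value)
    }
  }
  # ---- volume vs intensity ----------------------------------------------
  vi_ids <- intersect(pms$person_id, inten$person_id)
  ev1 <- if (length(cohorts) > 0) {
    co1 <- cohorts[[1]]$cohort
    as.integer(vi_ids %in% co1$person_id[co1$event == 1])
  } else NULL
  vol_int <- tryCatch(correlate_volume_intensity(
    pms$mean_steps[match(vi_ids, pms$person_id)],
    inten$mean_bout_cadence_60[match(vi_ids, inten$person_id)],
    event = ev1), error = function(e) NULL)
  bundle <- list(
    provenance = list(package_version =
                        as.character(utils::packageVersion("stepcourse")),
                      seed = sim$config$seed %||% NA,
                      exposure_mode = exposure_mode,
                      m_imputations = m_imputations),
    consort = consort,
    descriptives = descr,
    pct_months_excluded = pct_months_excluded,
    n_unmapped_codes = attr(pe, "n_unmapped"),
    phewas = phew,
    cohorts = lapply(cohorts, function(co)
      c(n = nrow(co$cohort), n_events = sum(co$cohort$event),
        n_excluded = nrow(co$excluded))),
    cooccurrence = if (length(cohorts) > 1) cooccurrence_counts(cohorts)
                   else NULL,
    contrasts = do.call(rbind, contrasts),
    chunk_tests = do.call(rbind, chunk_tests),
    hr_curves = do.call(rbind, hr_curves),
    incidence = do.call(rbind, incidence),
    trajectories = do.call(rbind, trajectories),
    ph_diagnostics = do.call(rbind, ph_tables),
    falsification = do.call(rbind, fals),
    intensity_models = do.call(rbind, intensity_models),
    volume_intensity = vol_int,
    ground_truth = sim$ground_truth[c("true_log_hr_per_1000",
                                      "true_hr_75_vs_25", "s25", "s75")])
  rownames(bundle$contrasts) <- NULL
  bundle
}

#' Write a result bundle to disk
#'
#' CSV tables, a JSON summary, and a plain-text log with stable filenames.
#'
#' @param bundle result of [run_full_analysis()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_report <- function(bundle, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stopf("cannot create output directory %s", dir)
  }
  paths <- character(0)
  wr <- function(obj, name) {
    if (is.null(obj) || (is.data.frame(obj) && nrow(obj) == 0)) return()
    p <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(as.data.frame(obj), p, row.names = FALSE)
    paths[[length(paths) + 1]] <<- p
  }
  wr(bundle$consort, "cohort_flow")
  wr(bundle$descriptives, "descriptives")
  wr(bundle$phewas, "phewas")
  wr(bundle$contrasts, "contrasts")
  wr(bundle$chunk_tests, "chunk_tests")
  wr(bundle$hr_curves, "hr_curves")
  wr(bundle$incidence, "cumulative_incidence")
  wr(bundle$trajectories, "trajectories")
  wr(bundle$ph_diagnostics, "ph_diagnostics")
  wr(bundle$falsification, "falsification")
  wr(bundle$intensity_models, "intensity_models")
  if (!is.null(bundle$cooccurrence)) {
    p <- file.path(dir, "cooccurrence.csv")
    utils::write.csv(bundle$cooccurrence, p)
    paths[[length(paths) + 1]] <- p
  }
  summ <- list(
    provenance = bundle$provenance,
    pct_months_excluded = bundle$pct_months_excluded,
    n_unmapped_codes = bundle$n_unmapped_codes,
    cohorts = bundle$cohorts,
    phewas_m_tests = attr(bundle$phewas, "m_tests"),
    phewas_alpha = attr(bundle$phewas, "alpha_bonferroni"),
    volume_intensity_rho = bundle$volume_intensity$rho %||% NA,
    ground_truth = bundle$ground_truth)
  pj <- file.path(dir, "summary.json")
  jsonlite::write_json(summ, pj, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  paths[[length(paths) + 1]] <- pj
  lg <- file.path(dir, "run.log")
  writeLines(c(sprintf("stepcourse %s", bundle$provenance$package_version),
               sprintf("seed %s, exposure mode %s, %d imputations",
                       bundle$provenance$seed,
                       bundle$provenance$exposure_mode,
                       bundle$provenance$m_imputations),
               sprintf("%.2f%% of months excluded (<15 valid days)",
                       bundle$pct_months_excluded),
               sprintf("%d unmapped condition codes dropped",
                       bundle$n_unmapped_codes %||% 0)), lg)
  paths[[length(paths) + 1]] <- lg
  invisible(unlist(paths))
}
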