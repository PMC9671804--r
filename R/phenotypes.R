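# EHR phenotype construction: ICD -> phecode mapping, incident cohorts with
# washout, censoring dates, and counting-process tables for time-varying
# Cox models.

#' Map ICD condition occurrences to first phecode occurrences
#'
#' Joins condition rows to the map on (vocabulary, code), drops and counts
#' unmapped codes, and keeps the earliest date per (person, phecode).
#'
#' @param conditions data.frame `person_id`, `date`, `code`, `vocabulary`
#'   (ICD9CM or ICD10CM).
#' @param map phecode map data.frame (see [gen_phecode_map_fixture()]).
#' @return data.frame `person_id`, `phecode`, `first_date`; the number of
#'   dropped unmapped rows is attached as attribute `n_unmapped`.
#' @export
map_events_to_phecodes <- function(conditions, map) {
  stopifnot(all(c("person_id", "date", "code", "vocabulary") %in%
                  names(conditions)))
  bad <- !conditions$vocabulary %in% c("ICD9CM", "ICD10CM")
  if (any(bad)) stopf("unknown vocabulary: %s",
                      paste(unique(conditions$vocabulary[bad]), collapse = ", "))
  if (anyNA(as.Date(conditions$date))) stopf("malformed dates in conditions")
  key_c <- paste(conditions$vocabulary, conditions$code)
  key_m <- paste(map$vocabulary, map$code)
  hit <- match(key_c, key_m)
  n_unmapped <- sum(is.na(hit))
  ok <- !is.na(hit)
  mapped <- data.frame(person_id = conditions$person_id[ok],
                       phecode = map$phecode[hit[ok]],
                       date = as.Date(conditions$date[ok]),
                       stringsAsFactors = FALSE)
  if (nrow(mapped) == 0) {
    out <- data.frame(person_id = character(), phecode = character(),
                      first_date = as.Date(character()))
    attr(out, "n_unmapped") <- n_unmapped
    return(out)
  }
  key <- paste(mapped$person_id, mapped$phecode, sep = "\r")
  first <- tapply(as.numeric(mapped$date), key, min)
  parts <- do.call(rbind, strsplit(names(first), "\r", fixed = TRUE))
  out <- data.frame(person_id = parts[, 1], phecode = parts[, 2],
                    first_date = as.Date(as.numeric(first),
                                         origin = "1970-01-01"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$person_id, out$phecode), ]
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Censoring date per person: last medical encounter
#'
#' The censoring date is the latest date across measurement, lab, procedure
#' and condition encounters. Condition occurrences may be supplied so that
#' diagnosis codes count as encounters.
#'
#' @param encounters data.frame `person_id`, `date`, `domain`.
#' @param conditions optional condition table; its rows are treated as
#'   domain "condition".
#' @return data.frame `person_id`, `censor_date`.
#' @export
censoring_date <- function(encounters, conditions = NULL) {
  keep <- encounters$domain %in% c("measurement", "lab", "procedure",
                                   "condition")
  enc <- encounters[keep, c("person_id", "date")]
  if (!is.null(conditions)) {
    enc <- rbind(enc, conditions[, c("person_id", "date")])
  }
  if (nrow(enc) == 0) stopf("no encounters")
  mx <- tapply(as.numeric(as.Date(enc$date)), enc$person_id, max)
  data.frame(person_id = names(mx),
             censor_date = as.Date(as.numeric(mx), origin = "1970-01-01"),
             stringsAsFactors = FALSE)
}

#' Build an incident-disease cohort with washout exclusions
#'
#' Persons whose first qualifying occurrence falls before monitoring start
#' (prevalent) or within the washout window are excluded for this outcome.
#' Otherwise the person contributes risk time from the washout end (late
#' entry) to the first post-washout occurrence (event) or the censoring
#' date. Combined phecodes are analysed as one outcome via the earliest
#' qualifying occurrence. Time is measured in 30-day months from each
#' person's monitoring start.
#'
#' @param phecode_events output of [map_events_to_phecodes()].
#' @param monitoring data.frame `person_id`, `start_date`.
#' @param censoring data.frame `person_id`, `censor_date` (see
#'   [censoring_date()]).
#' @param target_phecodes character vector; multiple entries are the
#'   combination set analysed as one condition.
#' @param washout_months washout length in 30-day months (default 6).
#' @return list: `cohort` (person_id, entry, exit, event), `excluded`
#'   (person_id, reason), `washout_months`.
#' @export
build_incident_cohort <- function(phecode_events, monitoring, censoring,
                                  target_phecodes, washout_months = 6) {
  if (washout_months <= 0) stopf("washout must be > 0")
  ev <- phecode_events[phecode_events$phecode %in% target_phecodes, ]
  if (nrow(ev) > 0 && !all(ev$person_id %in% monitoring$person_id)) {
    stopf("event for a person without a monitoring start")
  }
  first <- if (nrow(ev) > 0) {
    tapply(as.numeric(ev$first_date), ev$person_id, min)
  } else {
    stats::setNames(numeric(0), character(0))
  }
  start <- as.numeric(as.Date(monitoring$start_date))
  names(start) <- monitoring$person_id
  cens <- as.numeric(as.Date(censoring$censor_date))
  names(cens) <- censoring$person_id
  ids <- monitoring$person_id
  occ_m <- (unname(first[ids]) - start[ids]) / 30
  cen_m <- (unname(cens[ids]) - start[ids]) / 30
  reason <- rep(NA_character_, length(ids))
  reason[is.na(cen_m)] <- "no_encounters"
  has_occ <- !is.na(occ_m)
  reason[has_occ & occ_m < 0 & is.na(reason)] <- "prevalent_before_monitoring"
  reason[has_occ & occ_m >= 0 & occ_m <= washout_months &
           is.na(reason)] <- "occurrence_in_washout"
  event <- has_occ & is.na(reason)
  exit <- ifelse(event, occ_m, cen_m)
  reason[!event & !is.na(cen_m) & cen_m <= washout_months &
           is.na(reason)] <- "followup_shorter_than_washout"
  keep <- is.na(reason)
  cohort <- data.frame(person_id = ids[keep], entry = washout_months,
                       exit = exit[keep], event = as.integer(event[keep]),
                       stringsAsFactors = FALSE)
  excluded <- data.frame(person_id = ids[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE)
  # guard: a coded event on the exact washout boundary yields zero risk time
  zero <- cohort$exit <= cohort$entry
  if (any(zero)) {
    excluded <- rbind(excluded,
                      data.frame(person_id = cohort$person_id[zero],
                                 reason = "no_risk_time"))
    cohort <- cohort[!zero, , drop = FALSE]
  }
  rownames(cohort) <- NULL
  list(cohort = cohort, excluded = excluded, washout_months = washout_months)
}

#' Monthly exposures for a whole cohort (vectorised)
#'
#' Equivalent to applying [monthly_exposures()] per participant, computed in
#' one pass. Adds `last_valid_mean`, the most recent valid month's mean
#' steps carried forward (used as the month-mode exposure fallback for
#' event intervals).
#'
#' @param daily cohort daily-summary data.frame with `person_id`, `date`
#'   or `month_index`, `total_steps`, `wear_hours`, `is_valid`.
#' @param min_valid_days valid-month threshold (default 15).
#' @return data.frame keyed by (`person_id`, `month_index`).
#' @export
monthly_exposures_all <- function(daily, min_valid_days = 15) {
  pid_levels <- unique(daily$person_id)
  pi <- match(daily$person_id, pid_levels)
  if (is.null(daily$month_index)) {
    start <- tapply(as.numeric(daily$date), pi, min)
    daily$month_index <- floor((as.numeric(daily$date) - start[pi]) / 30)
  }
  v <- daily$is_valid & daily$total_steps >= 100
  key <- (pi - 1) * 1e6 + daily$month_index
  agg <- rowsum(cbind(steps = ifelse(v, daily$total_steps, 0),
                      wear = ifelse(v, daily$wear_hours, 0),
                      nvalid = as.numeric(v)), key)
  akey <- as.numeric(rownames(agg))
  maxm <- tapply(daily$month_index, pi, max)
  np <- length(pid_levels)
  gm <- sequence(maxm + 1L) - 1L
  gp <- rep(seq_len(np), maxm + 1L)
  gkey <- (gp - 1) * 1e6 + gm
  hit <- match(gkey, akey)
  nvalid <- ifelse(is.na(hit), 0, agg[hit, "nvalid"])
  ssum <- ifelse(is.na(hit), 0, agg[hit, "steps"])
  wsum <- ifelse(is.na(hit), 0, agg[hit, "wear"])
  mean_steps <- ifelse(nvalid > 0, ssum / nvalid, NA_real_)
  mean_wear <- ifelse(nvalid > 0, wsum / nvalid, NA_real_)
  cn <- stats::ave(nvalid, gp, FUN = cumsum)
  cs <- stats::ave(ssum, gp, FUN = cumsum)
  run <- ifelse(cn > 0, cs / cn, NA_real_)
  is_valid_month <- nvalid >= min_valid_days
  lvm_src <- ifelse(is_valid_month, mean_steps, NA_real_)
  lvm <- stats::ave(lvm_src, gp, FUN = function(x) {
    notna <- which(!is.na(x))
    if (length(notna) == 0) return(x)
    idx <- cummax(ifelse(!is.na(x), seq_along(x), 0))
    out <- rep(NA_real_, length(x))
    out[idx > 0] <- x[idx[idx > 0]]
    out
  })
  data.frame(person_id = pid_levels[gp], month_index = gm,
             n_valid_days = as.integer(nvalid), mean_steps = mean_steps,
             mean_wear_hours = mean_wear, is_valid_month = is_valid_month,
             running_mean_steps = run, last_valid_mean = lvm,
             stringsAsFactors = FALSE)
}

#' Build a counting-process table with time-varying exposures
#'
#' One (start, stop] row per retained month from washout entry to exit.
#' The exposure attached to interval (m, m+1] is computed from data
#' strictly before the interval: the running mean of valid days through
#' month m-1 (`exposure_mode = "running"`, default) or month m-1's mean
#' (`"month"`). A non-event interval is retained only when month m-1 is a
#' valid month (invalid months create risk-set gaps). The event interval is
#' always retained, using the most recent available exposure; persons whose
#' event interval has no prior exposure at all are dropped and logged.
#'
#' @param cohort_obj result of [build_incident_cohort()].
#' @param monthly result of [monthly_exposures_all()].
#' @param covariates baseline covariate data.frame keyed by `person_id`.
#' @param exposure_mode "running" or "month".
#' @return data.frame `person_id`, `start`, `stop`, `event`, `steps`
#'   (exposure, steps/day), `wear` (time-varying mean wear hours), plus the
#'   covariate columns. Attributes: `dropped_no_exposure` (person ids),
#'   `n_intervals_gap` (non-event intervals lost to invalid months),
#'   `n_intervals_possible`.
#' @export
build_counting_process <- function(cohort_obj, monthly, covariates = NULL,
                                   exposure_mode = c("running", "month")) {
  exposure_mode <- match.arg(exposure_mode)
  ch <- cohort_obj$cohort
  if (nrow(ch) == 0) stopf("empty cohort")
  m_start <- floor(ch$entry)
  m_end <- ceiling(ch$exit) - 1
  n_int <- pmax(m_end - m_start + 1L, 0L)
  ridx <- rep(seq_len(nrow(ch)), n_int)
  m <- sequence(n_int) - 1L + m_start[ridx]
  start <- pmax(m, ch$entry[ridx])
  stop_ <- pmin(m + 1, ch$exit[ridx])
  keep_len <- stop_ > start
  ridx <- ridx[keep_len]; m <- m[keep_len]
  start <- start[keep_len]; stop_ <- stop_[keep_len]
  is_event_row <- ch$event[ridx] == 1 & stop_ == ch$exit[ridx]
  pid_levels <- unique(monthly$person_id)
  mi <- match(ch$person_id[ridx], pid_levels)
  mkey <- (mi - 1) * 1e6 + (m - 1)          # month m-1 supplies exposure
  mhit <- match(mkey, (match(monthly$person_id, pid_levels) - 1) * 1e6 +
                  monthly$month_index)
  lag_valid <- !is.na(mhit) & monthly$is_valid_month[mhit]
  expo <- if (exposure_mode == "running") monthly$running_mean_steps[mhit]
          else ifelse(lag_valid, monthly$mean_steps[mhit], NA_real_)
  expo_fallback <- if (exposure_mode == "running")
    monthly$running_mean_steps[mhit] else monthly$last_valid_mean[mhit]
  wear <- monthly$mean_wear_hours[mhit]
  n_possible <- length(m)
  keep <- (lag_valid & !is.na(expo)) |
    (is_event_row & !is.na(expo_fallback))
  expo[is_event_row & !lag_valid] <- expo_fallback[is_event_row & !lag_valid]
  dropped_events <- unique(ch$person_id[ridx[is_event_row & !keep]])
  n_gap <- sum(!keep & !is_event_row)
  ridx <- ridx[keep]; m <- m[keep]; start <- start[keep]
  stop_ <- stop_[keep]; expo <- expo[keep]; wear <- wear[keep]
  is_event_row <- is_event_row[keep]
  drop_person <- ch$person_id[ridx] %in% dropped_events
  out <- data.frame(person_id = ch$person_id[ridx][!drop_person],
                    start = start[!drop_person], stop = stop_[!drop_person],
                    event = as.integer(is_event_row[!drop_person]),
                    steps = expo[!drop_person],
                    wear = ifelse(is.na(wear[!drop_person]), 0,
                                  wear[!drop_person]),
                    stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    hit <- match(out$person_id, covariates$person_id)
    out <- cbind(out, covariates[hit, setdiff(names(covariates), "person_id"),
                                 drop = FALSE])
    rownames(out) <- NULL
  }
  attr(out, "dropped_no_exposure") <- dropped_events
  attr(out, "n_intervals_gap") <- n_gap
  attr(out, "n_intervals_possible") <- n_possible
  out
}

#' Pairwise co-occurrence counts of incident outcomes
#'
#' Plain count table of persons with incident events for each pair of
#' outcomes (multimorbidity summary).
#'
#' @param cohorts named list of [build_incident_cohort()] results.
#' @return square matrix of co-occurrence counts (diagonal = event counts).
#' @export
cooccurrence_counts <- function(cohorts) {
  sets <- lapply(cohorts, function(co)
    co$cohort$person_id[co$cohort$event == 1])
  n <- length(sets)
  m <- matrix(0L, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    m[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  }
  m
}

#' Per-person overall mean daily steps over valid days
#'
#' @param daily cohort daily-summary data.frame.
#' @return data.frame `person_id`, `mean_steps`, `n_valid_days`.
#' @export
person_mean_steps <- function(daily) {
  iv <- which(daily$is_valid & daily$total_steps >= 100)
  ids <- unique(daily$person_id[iv])
  pi <- match(daily$person_id[iv], ids)
  agg <- rowsum(cbind(s = daily$total_steps[iv], n = 1), pi)
  data.frame(person_id = ids[as.integer(rownames(agg))],
             mean_steps = agg[, "s"] / agg[, "n"],
             n_valid_days = as.integer(agg[, "n"]), stringsAsFactors = FALSE)
}

#' Monitoring span filter
#'
#' Participants need at least `min_months` 30-day months between their first
#' and last valid day to enter any analysis.
#'
#' @param daily cohort daily-summary data.frame.
#' @param min_months minimum span (default 6).
#' @return data.frame `person_id`, `span_months`, `included`.
#' @export
monitoring_span <- function(daily, min_months = 6) {
  iv <- which(daily$is_valid & daily$total_steps >= 100)
  ids <- unique(daily$person_id[iv])
  pi <- match(daily$person_id[iv], ids)
  dn <- as.numeric(daily$date[iv])
  o <- order(pi, dn)
  po <- pi[o]; do_ <- dn[o]
  first_at <- !duplicated(po)
  last_at <- !duplicated(po, fromLast = TRUE)
  span <- (do_[last_at] - do_[first_at]) / 30
  data.frame(person_id = ids[po[first_at]], span_months = span,
             included = span >= min_months, stringsAsFactors = FALSE)
}
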