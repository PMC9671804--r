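# Wearable step-stream processing: valid days, wear time, cadence bouts,
# monthly time-varying exposures.

#' Detect cadence bouts in one day of minute-level steps
#'
#' A bout is a maximal run of consecutive minutes each at or above
#' `cadence_threshold` steps/min, kept only if it lasts at least `min_len`
#' minutes. The conventional thresholds are 60 steps/min (slow walking) and
#' 100 steps/min (moderate-to-vigorous).
#'
#' @param day_minutes numeric vector of steps per minute, in chronological
#'   order over a single day (missing trailing/leading minutes may be
#'   omitted; they count as zeros).
#' @param cadence_threshold minimum steps per minute, > 0.
#' @param min_len minimum bout length in minutes (>= 1; default 2).
#' @return data.frame with one row per bout: `start`, `end` (1-based minute
#'   indices, inclusive), `n_minutes`, `total_steps`, `mean_cadence`.
#' @examples
#' detect_bouts(c(70, 65, 0, 90, 95, 100), 60)
#' @export
detect_bouts <- function(day_minutes, cadence_threshold, min_len = 2) {
  if (min_len < 1) stopf("min_len must be >= 1, got %s", min_len)
  if (cadence_threshold <= 0) stopf("cadence_threshold must be > 0")
  if (any(day_minutes < 0)) stopf("negative steps in minute stream")
  empty <- data.frame(start = integer(), end = integer(),
                      n_minutes = integer(), total_steps = numeric(),
                      mean_cadence = numeric())
  if (length(day_minutes) == 0) return(empty)
  above <- day_minutes >= cadence_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  if (!any(keep)) return(empty)
  starts <- starts[keep]; ends <- ends[keep]
  tot <- vapply(seq_along(starts),
                function(i) sum(day_minutes[starts[i]:ends[i]]), numeric(1))
  n <- ends - starts + 1L
  data.frame(start = starts, end = ends, n_minutes = n,
             total_steps = tot, mean_cadence = tot / n)
}

# Normalise one day's minute records to (minute_of_day, steps).
.day_minutes <- function(day) {
  if (is.numeric(day)) {
    if (length(day) > 1440) stopf("more than 1,440 minutes in one day")
    return(list(minute = seq_along(day) - 1L, steps = as.numeric(day),
                date = NA))
  }
  stopifnot(is.data.frame(day), "steps" %in% names(day))
  steps <- as.numeric(day$steps)
  if (!is.null(day$timestamp)) {
    ts <- day$timestamp
    d <- unique(as.Date(ts, tz = "UTC"))
    if (length(d) > 1) stopf("summarize_day expects a single calendar day")
    lt <- as.POSIXlt(ts, tz = "UTC")
    minute <- lt$hour * 60L + lt$min
  } else if (!is.null(day$minute)) {
    minute <- as.integer(day$minute)
    d <- if (!is.null(day$date)) unique(day$date) else NA
    if (length(d) > 1) stopf("summarize_day expects a single calendar day")
  } else {
    stopf("day must have a 'timestamp' or 'minute' column")
  }
  if (any(minute < 0 | minute > 1439)) stopf("timestamps outside the day")
  if (anyDuplicated(minute)) stopf("duplicate minutes in one day")
  if (nrow(day) > 1440) stopf("more than 1,440 minutes in one day")
  o <- order(minute)
  list(minute = minute[o], steps = steps[o], date = d)
}

#' Summarise one day of a minute-level step stream
#'
#' Computes the daily metrics used for valid-day screening and exposure
#' construction: total steps, wear hours (number of distinct clock hours
#' containing at least one non-zero minute), bout minutes and bout steps at
#' the 60 and 100 steps/min cadence thresholds, and the validity flag. A
#' valid day has at least 10 wear hours and at least 100 steps.
#'
#' @param day either a numeric vector of per-minute steps (assumed to start
#'   at midnight) or a data.frame with `steps` plus either `timestamp`
#'   (POSIXct) or `minute` (0-1439) and optionally `date`.
#' @return one-row data.frame: `date`, `total_steps`, `wear_hours`,
#'   `n_bout_minutes_60`, `bout_steps_60`, `n_bout_minutes_100`,
#'   `bout_steps_100`, `is_valid`.
#' @export
summarize_day <- function(day) {
  dm <- .day_minutes(day)
  if (any(dm$steps < 0)) stopf("negative steps")
  # place minutes on the full 1,440-slot grid; absent slots are zeros
  grid <- numeric(1440)
  grid[dm$minute + 1L] <- dm$steps
  total <- sum(grid)
  wear <- length(unique((dm$minute[dm$steps > 0]) %/% 60L))
  b60 <- detect_bouts(grid, 60)
  b100 <- detect_bouts(grid, 100)
  data.frame(
    date = if (inherits(dm$date, "Date")) dm$date else as.Date(NA),
    total_steps = total,
    wear_hours = wear,
    n_bout_minutes_60 = sum(b60$n_minutes),
    bout_steps_60 = sum(b60$total_steps),
    n_bout_minutes_100 = sum(b100$n_minutes),
    bout_steps_100 = sum(b100$total_steps),
    is_valid = wear >= 10 && total >= 100
  )
}

#' Summarise every day of a minute-level step stream
#'
#' @param series data.frame with columns `participant_id` (optional),
#'   `timestamp` (POSIXct) and `steps`.
#' @return data.frame of daily summaries (one row per calendar day present
#'   in the stream), ordered by date.
#' @export
summarize_days <- function(series) {
  stopifnot(is.data.frame(series), all(c("timestamp", "steps") %in% names(series)))
  dts <- as.Date(series$timestamp, tz = "UTC")
  out <- lapply(split(seq_len(nrow(series)), dts), function(idx) {
    s <- summarize_day(series[idx, c("timestamp", "steps")])
    s$date <- as.Date(dts[idx[1]])
    s
  })
  res <- do.call(rbind, out)
  res <- res[order(res$date), , drop = FALSE]
  rownames(res) <- NULL
  if (!is.null(series$participant_id)) {
    res <- cbind(participant_id = series$participant_id[1], res)
  }
  res
}

#' Drop sub-threshold days from a daily summary table
#'
#' Days with fewer than `min_steps` total steps are removed before any other
#' computation; they represent device-on-but-unworn artefacts.
#'
#' @param daily daily-summary data.frame (from [summarize_days()] or the
#'   synthetic generator).
#' @param min_steps minimum total steps to retain a day (default 100).
#' @return filtered daily table; the number of dropped days is attached as
#'   attribute `n_dropped_low_steps`.
#' @export
filter_low_step_days <- function(daily, min_steps = 100) {
  keep <- daily$total_steps >= min_steps
  out <- daily[keep, , drop = FALSE]
  attr(out, "n_dropped_low_steps") <- sum(!keep)
  out
}

#' Pooled bout-cadence intensity over valid days
#'
#' Pools bouts across all valid days as total bout steps divided by total
#' bout minutes (time-weighted), at both the 60 and 100 steps/min
#' thresholds. Returns NA for a threshold with zero bout minutes.
#'
#' @param daily daily-summary data.frame.
#' @return one-row data.frame `mean_bout_cadence_60`, `mean_bout_cadence_100`,
#'   plus the pooled minute counts.
#' @export
intensity_summary <- function(daily) {
  v <- daily[daily$is_valid, , drop = FALSE]
  if (nrow(v) == 0) stopf("no valid days")
  pool <- function(stepcol, mincol) {
    mins <- sum(v[[mincol]], na.rm = TRUE)
    if (mins == 0) return(c(NA_real_, 0))
    c(sum(v[[stepcol]], na.rm = TRUE) / mins, mins)
  }
  p60 <- pool("bout_steps_60", "n_bout_minutes_60")
  p100 <- pool("bout_steps_100", "n_bout_minutes_100")
  data.frame(mean_bout_cadence_60 = p60[1], n_bout_minutes_60 = p60[2],
             mean_bout_cadence_100 = p100[1], n_bout_minutes_100 = p100[2])
}

#' Bin daily summaries into 30-day monthly exposures
#'
#' Months are consecutive 30-day blocks counted from `monitoring_start`
#' (month 0 covers days 0-29). Low-step days are dropped first; monthly
#' means use valid days only; a month is valid with at least 15 valid days;
#' `running_mean_steps` is the valid-day-weighted mean of all valid days up
#' to and including the month.
#'
#' @param daily daily-summary data.frame with `date`, `total_steps`,
#'   `wear_hours`, `is_valid`.
#' @param monitoring_start Date; defaults to the earliest day present.
#' @param min_valid_days minimum valid days for a valid month (default 15).
#' @return data.frame with one row per month index from 0 to the last
#'   monitored month: `month_index`, `n_valid_days`, `mean_steps`,
#'   `mean_wear_hours`, `is_valid_month`, `running_mean_steps`.
#' @export
monthly_exposures <- function(daily, monitoring_start = NULL,
                              min_valid_days = 15) {
  if (nrow(daily) == 0) stopf("empty daily summary table")
  daily <- filter_low_step_days(daily)
  if (nrow(daily) == 0) stopf("no days remain after the low-step filter")
  start <- monitoring_start %||% min(daily$date)
  offs <- as.numeric(daily$date - start)
  if (any(offs < 0)) stopf("days before monitoring_start")
  m <- floor(offs / 30)
  maxm <- max(m)
  v <- daily$is_valid
  idx <- factor(m, levels = 0:maxm)
  nvalid <- as.integer(tapply(v, idx, sum, default = 0))
  sum_steps <- as.numeric(tapply(ifelse(v, daily$total_steps, 0), idx, sum,
                                 default = 0))
  sum_wear <- as.numeric(tapply(ifelse(v, daily$wear_hours, 0), idx, sum,
                                default = 0))
  mean_steps <- ifelse(nvalid > 0, sum_steps / nvalid, NA_real_)
  mean_wear <- ifelse(nvalid > 0, sum_wear / nvalid, NA_real_)
  cum_n <- cumsum(nvalid)
  run <- ifelse(cum_n > 0, cumsum(sum_steps) / cum_n, NA_real_)
  data.frame(month_index = 0:maxm,
             n_valid_days = nvalid,
             mean_steps = mean_steps,
             mean_wear_hours = mean_wear,
             is_valid_month = nvalid >= min_valid_days,
             running_mean_steps = run)
}

#' Average daily steps over a window of months from monitoring start
#'
#' Used for baseline exposure (first 3 or 6 months) and trajectory windows
#' (0-3, 3-6, 6-12, 12-24 months). The window is `[from_month, to_month)`
#' in 30-day months; the mean is over valid days only.
#'
#' @param daily daily-summary data.frame.
#' @param from_month,to_month window bounds in months (to_month exclusive).
#' @param monitoring_start Date; defaults to earliest day present.
#' @return mean steps/day over valid days in the window, or NA if none.
#' @export
window_average <- function(daily, from_month, to_month,
                           monitoring_start = NULL) {
  if (to_month <= from_month) stopf("inverted window")
  daily <- filter_low_step_days(daily)
  start <- monitoring_start %||% min(daily$date)
  offs <- as.numeric(daily$date - start)
  sel <- daily$is_valid & offs >= from_month * 30 & offs < to_month * 30
  if (!any(sel)) return(NA_real_)
  mean(daily$total_steps[sel])
}

#' Rank correlation of step volume with bout-cadence intensity
#'
#' Spearman correlation between per-participant mean daily steps and mean
#' bout cadence, on pairwise-complete observations, plus a quartile
#' cross-tabulation of the two (with per-cell incident rates when an event
#' indicator is supplied) for descriptive risk-gradient output.
#'
#' @param mean_steps numeric vector, one per participant.
#' @param mean_cadence numeric vector, same length.
#' @param event optional 0/1 vector; per-cell incident rates are added.
#' @return list with `rho`, `p_value`, `n`, and `quartile_table`.
#' @export
correlate_volume_intensity <- function(mean_steps, mean_cadence,
                                       event = NULL) {
  ok <- is.finite(mean_steps) & is.finite(mean_cadence)
  if (sum(ok) < 3) stopf("fewer than 3 complete pairs")
  ct <- stats::cor.test(mean_steps[ok], mean_cadence[ok],
                        method = "spearman", exact = FALSE)
  qs <- function(x) cut(x, breaks = stats::quantile(x, probs = 0:4 / 4),
                        include.lowest = TRUE, labels = paste0("Q", 1:4))
  sq <- qs(mean_steps[ok]); cq <- qs(mean_cadence[ok])
  tab <- table(steps = sq, cadence = cq)
  out <- list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok),
              quartile_table = tab)
  if (!is.null(event)) {
    ev <- event[ok]
    rate <- tapply(ev, list(sq, cq), mean)
    out$incident_rate_table <- rate
  }
  out
}
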