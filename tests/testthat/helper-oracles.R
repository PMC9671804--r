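# Independent brute-force oracles used across tests. These deliberately use
# naive scans/loops rather than the package's own algorithms.

# Bout detection by explicit minute-by-minute scan.
bout_oracle <- function(x, thr, min_len = 2) {
  runs <- list()
  i <- 1
  n <- length(x)
  while (i <= n) {
    if (x[i] >= thr) {
      j <- i
      while (j < n && x[j + 1] >= thr) j <- j + 1
      if (j - i + 1 >= min_len) {
        runs[[length(runs) + 1]] <- c(start = i, end = j,
                                      total = sum(x[i:j]))
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(runs) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      total = numeric()))
  }
  as.data.frame(do.call(rbind, runs))
}

# Wear hours by explicit per-clock-hour scan of a 1,440-slot day.
wear_oracle <- function(x1440) {
  sum(vapply(0:23, function(h) any(x1440[(h * 60 + 1):(h * 60 + 60)] > 0),
             logical(1)))
}

# Efron-ties Cox partial log-likelihood for counting-process data with a
# single covariate, by direct risk-set enumeration.
efron_loglik <- function(beta, start, stop, event, x) {
  eta <- x * beta
  ll <- 0
  for (t in sort(unique(stop[event == 1]))) {
    D <- which(event == 1 & stop == t)
    R <- which(start < t & stop >= t)
    d <- length(D)
    sumD <- sum(exp(eta[D]))
    sumR <- sum(exp(eta[R]))
    ll <- ll + sum(eta[D]) -
      sum(log(sumR - (seq_len(d) - 1) / d * sumD))
  }
  ll
}

# Fit a toy, regenerating on the rare perfectly-separated draw where the
# partial likelihood has no finite maximiser and the fitter overflows.
fit_toy <- function() {
  for (try in 1:20) {
    cp <- random_cp_toy()
    f <- tryCatch(suppressWarnings(fit_cox_tv(cp)),
                  error = function(e) NULL)
    if (!is.null(f)) return(list(cp = cp, fit = f))
  }
  stop("could not draw a fittable toy in 20 tries")
}

# Random small counting-process toy with at least one event and a
# non-constant covariate.
random_cp_toy <- function() {
  repeat {
    np <- sample(2:5, 1)
    rows <- list()
    for (p in seq_len(np)) {
      k <- sample(1:3, 1)
      cuts <- sort(sample(seq(0.5, 10, by = 0.5), k + 1))
      for (j in seq_len(k)) {
        rows[[length(rows) + 1]] <- data.frame(
          person_id = paste0("p", p), start = cuts[j], stop = cuts[j + 1],
          event = 0L, steps = round(stats::runif(1, -2, 2), 2))
      }
      if (stats::runif(1) < 0.6) {
        rows[[length(rows)]]$event <- 1L
      }
    }
    cp <- do.call(rbind, rows)
    if (sum(cp$event) >= 1 && sum(cp$event) <= 3 &&
        stats::var(cp$steps) > 0) {
      return(cp)
    }
  }
}

# Small deterministic daily-summary table builder for fixture tests.
make_daily <- function(person_id, dates, steps, wear = 12,
                       valid = NULL) {
  n <- length(dates)
  steps <- rep_len(steps, n)
  wear <- rep_len(wear, n)
  v <- if (is.null(valid)) wear >= 10 & steps >= 100 else rep_len(valid, n)
  data.frame(person_id = person_id, date = as.Date(dates),
             total_steps = steps, wear_hours = wear,
             n_bout_minutes_60 = 0, bout_steps_60 = 0,
             n_bout_minutes_100 = 0, bout_steps_100 = 0,
             is_valid = v, worn = steps > 0, stringsAsFactors = FALSE)
}
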