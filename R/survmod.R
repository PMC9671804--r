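# Time-varying Cox machinery: restricted cubic splines with AIC knot
# selection, chunk tests, HR curves and percentile contrasts, cumulative
# incidence, and proportional-hazards diagnostics.

#' Default restricted-cubic-spline knot placement
#'
#' Standard quantile placement on the exposure distribution: 3 knots at
#' 0.10/0.50/0.90, 4 at 0.05/0.35/0.65/0.95, 5 at 0.05/0.275/0.50/0.725/0.95.
#'
#' @param x exposure values (pooled person-month scale).
#' @param k number of knots (3, 4 or 5).
#' @return numeric vector of knot locations.
#' @export
rcs_knots <- function(x, k) {
  probs <- switch(as.character(k),
                  "3" = c(0.10, 0.50, 0.90),
                  "4" = c(0.05, 0.35, 0.65, 0.95),
                  "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
                  stopf("k must be 3, 4 or 5"))
  kn <- unname(stats::quantile(x, probs, na.rm = TRUE, type = 7))
  if (any(diff(kn) <= 0)) stopf("degenerate exposure distribution: tied knots")
  kn
}

#' Restricted cubic spline basis (truncated-power parameterisation)
#'
#' k knots yield k-1 columns: the first is x itself; the remaining k-2 are
#' truncated cubic terms constrained so the fitted function is linear beyond
#' the boundary knots, scaled by (t_k - t_1)^2 for numerical balance.
#'
#' @param x numeric vector.
#' @param knots strictly increasing knot locations (length >= 3).
#' @return matrix with k-1 columns and attribute `knots`.
#' @export
rcs_basis <- function(x, knots) {
  knots <- as.numeric(knots)
  if (length(knots) < 3) stopf("need at least 3 knots")
  if (any(diff(knots) <= 0)) stopf("knots must be strictly increasing")
  k <- length(knots)
  tk <- knots[k]; tk1 <- knots[k - 1]; t1 <- knots[1]
  norm <- (tk - t1)^2
  cub <- function(u) pmax(u, 0)^3
  out <- matrix(NA_real_, length(x), k - 1)
  out[, 1] <- x
  for (j in seq_len(k - 2)) {
    tj <- knots[j]
    out[, j + 1] <- (cub(x - tj) -
                       cub(x - tk1) * (tk - tj) / (tk - tk1) +
                       cub(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
  }
  colnames(out) <- c("x", paste0("x'", strrep("'", seq_len(k - 2) - 1)))
  attr(out, "knots") <- knots
  out
}

#' Covariate sets of the standard model suite
#'
#' Model 1: time-varying steps, age, race, sex. Model 2 adds systolic blood
#' pressure, CAD, cancer, smoking, education, alcohol and BMI. Model 3 adds
#' time-varying wear hours; Models 4 and 5 add baseline steps averaged over
#' the first 3 and 6 months respectively.
#'
#' @return named list of covariate-column vectors.
#' @export
model_suite <- function() {
  m1 <- c("age", "race", "sex")
  m2 <- c(m1, "sbp", "cad", "cancer", "smoking", "education", "alcohol",
          "bmi")
  list(M1 = m1, M2 = m2, M3 = c(m2, "wear"),
       M4 = c(m2, "baseline_steps_3mo"), M5 = c(m2, "baseline_steps_6mo"))
}

# Expand covariates to a numeric design matrix (factors -> dummies) and
# remember column summaries for reference profiles.
.design <- function(data, covariates) {
  if (length(covariates) == 0) {
    return(list(mat = matrix(nrow = nrow(data), ncol = 0),
                profile = numeric(0)))
  }
  missing_cols <- setdiff(covariates, names(data))
  if (length(missing_cols) > 0) {
    stopf("covariates not in table: %s", paste(missing_cols, collapse = ", "))
  }
  df <- data[, covariates, drop = FALSE]
  for (v in names(df)) if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  mm <- stats::model.matrix(~ ., df)[, -1, drop = FALSE]
  colnames(mm) <- make.names(colnames(mm))
  # reference profile: median for continuous, modal category for dummies
  prof <- vapply(seq_len(ncol(mm)), function(j) {
    col <- mm[, j]
    if (all(col %in% c(0, 1))) as.numeric(stats::median(col) > 0.5)
    else stats::median(col)
  }, numeric(1))
  names(prof) <- colnames(mm)
  list(mat = mm, profile = prof)
}

#' Fit a time-varying Cox model on a counting-process table
#'
#' Maximises the counting-process partial likelihood (Efron ties by
#' default) with the exposure entered linearly or as a restricted cubic
#' spline, optional adjustment covariates, an optional linear BMI-by-steps
#' interaction, and an optional second spline for bout-cadence intensity.
#'
#' @param cp counting-process data.frame from [build_counting_process()]
#'   (columns `start`, `stop`, `event`, `steps`, plus covariates).
#' @param knots NULL for a linear exposure, an integer k in 3:5 (quantile
#'   placement via [rcs_knots()]), or an explicit knot vector.
#' @param covariates character vector of adjustment columns.
#' @param bmi_interaction add a linear `bmi:steps` interaction term.
#' @param intensity_col optional column with a time-varying (or baseline)
#'   bout-cadence intensity entered as its own spline (same k as `knots`,
#'   or linear when `knots` is NULL).
#' @param ties "efron" (default) or "breslow".
#' @return object of class `cox_fit`: coefficients, covariance, log partial
#'   likelihood, AIC, term groups, knots, reference profile and the
#'   underlying `survival::coxph` fit.
#' @export
fit_cox_tv <- function(cp, knots = NULL, covariates = character(),
                       bmi_interaction = FALSE, intensity_col = NULL,
                       ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (sum(cp$event) < 1) stopf("no events in counting-process table")
  keep <- stats::complete.cases(cp[, unique(c("start", "stop", "event",
                                              "steps", covariates,
                                              intensity_col)),
                                   drop = FALSE])
  cp <- cp[keep, , drop = FALSE]
  if (!is.null(knots) && length(knots) == 1) {
    knots <- rcs_knots(cp$steps, knots)
  }
  if (is.null(knots)) {
    X <- matrix(cp$steps, ncol = 1, dimnames = list(NULL, "steps"))
  } else {
    X <- rcs_basis(cp$steps, knots)
    colnames(X) <- c("steps", paste0("steps_nl", seq_len(ncol(X) - 1)))
  }
  exposure_terms <- colnames(X)
  nonlinear_terms <- setdiff(exposure_terms, "steps")
  intensity_terms <- character(0)
  int_knots <- NULL
  if (!is.null(intensity_col)) {
    xi <- cp[[intensity_col]]
    if (is.null(knots)) {
      XI <- matrix(xi, ncol = 1, dimnames = list(NULL, "intensity"))
    } else {
      int_knots <- rcs_knots(xi, length(knots))
      XI <- rcs_basis(xi, int_knots)
      colnames(XI) <- c("intensity",
                        paste0("intensity_nl", seq_len(ncol(XI) - 1)))
    }
    intensity_terms <- colnames(XI)
    X <- cbind(X, XI)
  }
  des <- .design(cp, covariates)
  if (ncol(des$mat) > 0) X <- cbind(X, des$mat)
  interaction_terms <- character(0)
  if (bmi_interaction) {
    if (!"bmi" %in% covariates) stopf("bmi_interaction needs 'bmi' covariate")
    X <- cbind(X, bmi_x_steps = cp$bmi * cp$steps)
    interaction_terms <- "bmi_x_steps"
  }
  const <- apply(X, 2, function(c) stats::var(c) == 0)
  if (any(const)) stopf("constant column(s): %s",
                        paste(colnames(X)[const], collapse = ", "))
  colnames(X) <- make.names(colnames(X))
  dd <- as.data.frame(X)
  dd$.start <- cp$start; dd$.stop <- cp$stop; dd$.event <- cp$event
  f <- stats::as.formula(paste("survival::Surv(.start, .stop, .event) ~",
                               paste(colnames(X), collapse = " + ")))
  fit <- survival::coxph(f, data = dd, ties = ties,
                         control = survival::coxph.control(iter.max = 50))
  dimnames(fit$var) <- list(colnames(X), colnames(X))
  ll <- fit$loglik[length(fit$loglik)]
  p <- length(fit$coefficients)
  structure(list(
    coef = fit$coefficients, vcov = fit$var, loglik = ll,
    aic = -2 * ll + 2 * p, n = fit$n, n_events = fit$nevent,
    converged = is.null(fit$info) || fit$iter < 50,
    knots = knots, intensity_knots = int_knots,
    exposure_terms = exposure_terms, nonlinear_terms = nonlinear_terms,
    intensity_terms = intensity_terms,
    interaction_terms = interaction_terms,
    covariate_profile = des$profile, ties = ties,
    steps_range = range(cp$steps), fit = fit), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Time-varying Cox fit: %d rows, %d events, %d terms\n",
              x$n, x$n_events, length(x$coef)))
  cat(sprintf("log partial likelihood %.3f, AIC %.2f, knots: %s\n",
              x$loglik, x$aic,
              if (is.null(x$knots)) "none (linear)" else
                paste(round(x$knots), collapse = ", ")))
  print(round(cbind(coef = x$coef, se = sqrt(diag(x$vcov))), 6))
  invisible(x)
}

#' Choose the spline fit with the lowest AIC
#'
#' @param fits list of `cox_fit` objects fitted to the same data (e.g. with
#'   3, 4 and 5 knots); ties are broken toward fewer parameters.
#' @return the selected `cox_fit` with attribute `aic_table`.
#' @export
select_by_aic <- function(fits) {
  stopifnot(length(fits) >= 1)
  nev <- vapply(fits, function(f) f$n_events, numeric(1))
  if (length(unique(nev)) != 1) stopf("fits have differing event counts")
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  p <- vapply(fits, function(f) length(f$coef), numeric(1))
  best <- order(aic, p)[1]
  out <- fits[[best]]
  attr(out, "aic_table") <- data.frame(
    fit = seq_along(fits), n_params = p, aic = aic,
    selected = seq_along(fits) == best)
  out
}

#' Joint Wald chunk test on a block of coefficients
#'
#' Computes beta' V^-1 beta on the named subset: used for the overall
#' exposure association (all spline terms) and for nonlinearity (the
#' nonlinear terms only).
#'
#' @param fit a `cox_fit`.
#' @param terms character vector of coefficient names, or one of the
#'   shortcuts "exposure", "nonlinear", "intensity".
#' @return list `statistic`, `df`, `p_value`, `terms`.
#' @export
wald_chunk_test <- function(fit, terms = "exposure") {
  if (length(terms) == 1 && terms %in% c("exposure", "nonlinear",
                                         "intensity")) {
    terms <- switch(terms, exposure = fit$exposure_terms,
                    nonlinear = fit$nonlinear_terms,
                    intensity = fit$intensity_terms)
  }
  if (length(terms) == 0) {
    return(list(statistic = NA_real_, df = 0L, p_value = NA_real_,
                terms = character(0)))
  }
  if (!all(terms %in% names(fit$coef))) stopf("terms not in fit")
  b <- fit$coef[terms]
  V <- fit$vcov[terms, terms, drop = FALSE]
  Vi <- tryCatch(solve(V), error = function(e)
    stopf("singular sub-covariance for chunk test"))
  stat <- drop(t(b) %*% Vi %*% b)
  df <- length(b)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE), terms = terms)
}

# Contrast vector (full coefficient length) for exposure value s vs ref.
.exposure_contrast <- function(fit, s, ref) {
  d <- stats::setNames(numeric(length(fit$coef)), names(fit$coef))
  if (is.null(fit$knots)) {
    d["steps"] <- s - ref
  } else {
    bs <- rcs_basis(c(s, ref), fit$knots)
    d[fit$exposure_terms] <- bs[1, ] - bs[2, ]
  }
  if (length(fit$interaction_terms) > 0) {
    # interaction evaluated at the profile's BMI
    bmi_ref <- fit$covariate_profile[["bmi"]]
    d["bmi_x_steps"] <- bmi_ref * (s - ref)
  }
  d
}

#' Hazard-ratio curve over a grid of exposure values
#'
#' HR(s) = exp(f(s) - f(ref)) with delta-method (Wald) confidence
#' intervals; HR at the reference is exactly 1.
#'
#' @param fit a `cox_fit`.
#' @param s_grid exposure grid (steps/day).
#' @param reference reference steps/day (typically the cohort median).
#' @param conf confidence level (default 0.95).
#' @return data.frame `steps`, `log_hr`, `se`, `hr`, `lower`, `upper`,
#'   `extrapolated`.
#' @export
hr_curve <- function(fit, s_grid, reference, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  res <- t(vapply(s_grid, function(s) {
    d <- .exposure_contrast(fit, s, reference)
    lhr <- sum(d * fit$coef)
    se <- sqrt(drop(t(d) %*% fit$vcov %*% d))
    c(lhr, se)
  }, numeric(2)))
  data.frame(steps = s_grid, log_hr = res[, 1], se = res[, 2],
             hr = exp(res[, 1]),
             lower = exp(res[, 1] - z * res[, 2]),
             upper = exp(res[, 1] + z * res[, 2]),
             extrapolated = s_grid < fit$steps_range[1] |
               s_grid > fit$steps_range[2])
}

#' Hazard ratio contrasting the 75th vs 25th exposure percentile
#'
#' Percentiles are computed from person-level mean daily steps within the
#' outcome cohort (or taken directly via `s25`/`s75`).
#'
#' @param fit a `cox_fit`.
#' @param person_steps person-level mean daily steps of cohort members
#'   (used when `s25`/`s75` are not given).
#' @param s25,s75 explicit percentile values (steps/day).
#' @param conf confidence level.
#' @return list `s25`, `s75`, `hr`, `lower`, `upper`, `log_hr`, `se`,
#'   `p_value`.
#' @export
hr_contrast <- function(fit, person_steps = NULL, s25 = NULL, s75 = NULL,
                        conf = 0.95) {
  if (is.null(s25) || is.null(s75)) {
    if (is.null(person_steps)) stopf("need person_steps or explicit s25/s75")
    q <- stats::quantile(person_steps, c(0.25, 0.75), na.rm = TRUE)
    s25 <- unname(q[1]); s75 <- unname(q[2])
  }
  if (s75 <= s25) stopf("degenerate exposure distribution")
  d <- .exposure_contrast(fit, s75, s25)
  lhr <- sum(d * fit$coef)
  se <- sqrt(drop(t(d) %*% fit$vcov %*% d))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(s25 = s25, s75 = s75, log_hr = lhr, se = se, hr = exp(lhr),
       lower = exp(lhr - z * se), upper = exp(lhr + z * se),
       p_value = 2 * stats::pnorm(-abs(lhr / se)))
}

#' Cumulative incidence at fixed exposure values
#'
#' Breslow baseline cumulative hazard from the fitted model, evaluated at a
#' covariate reference profile (median continuous covariates, modal
#' categories) with the exposure held at each requested value:
#' F(t|s) = 1 - exp(-Lambda0(t) exp(lp(s, profile))). Confidence bounds use
#' the delta method on the linear predictor. Time is measured in 30-day
#' months from monitoring start; `years` are converted at 365.25/30 months
#' per year. Because entry begins at the washout end, F is the incidence
#' conditional on being event-free at entry.
#'
#' @param fit a `cox_fit`.
#' @param s_values exposure values (steps/day) to hold fixed.
#' @param years horizons in years (default 3, 5, 7).
#' @param conf confidence level.
#' @return data.frame `steps`, `years`, `incidence`, `lower`, `upper`.
#' @export
cumulative_incidence <- function(fit, s_values, years = c(3, 5, 7),
                                 conf = 0.95) {
  if (!fit$converged) stopf("fit did not converge")
  bh <- survival::basehaz(fit$fit, centered = TRUE)
  t_months <- years * 365.25 / 30
  if (any(t_months > max(bh$time))) {
    stopf("requested horizon beyond observed follow-up")
  }
  H0c <- stats::approx(bh$time, bh$hazard, xout = t_months, rule = 2)$y
  # re-reference the centered baseline to our covariate profile
  prof <- fit$covariate_profile
  means <- fit$fit$means
  z <- stats::qnorm(1 - (1 - conf) / 2)
  rows <- list()
  for (s in s_values) {
    xb <- stats::setNames(numeric(length(fit$coef)), names(fit$coef))
    if (is.null(fit$knots)) xb["steps"] <- s
    else xb[fit$exposure_terms] <- rcs_basis(s, fit$knots)[1, ]
    if (length(fit$intensity_terms) > 0) {
      # hold intensity at its mean (coxph centering scale)
      xb[fit$intensity_terms] <- means[fit$intensity_terms]
    }
    if (length(prof) > 0) xb[names(prof)] <- prof
    if (length(fit$interaction_terms) > 0) {
      xb["bmi_x_steps"] <- prof[["bmi"]] * s
    }
    dlp <- xb - means
    lp <- sum(dlp * fit$coef)
    se <- sqrt(drop(t(dlp) %*% fit$vcov %*% dlp))
    Fmid <- 1 - exp(-H0c * exp(lp))
    Flo <- 1 - exp(-H0c * exp(lp - z * se))
    Fhi <- 1 - exp(-H0c * exp(lp + z * se))
    rows[[length(rows) + 1]] <- data.frame(
      steps = s, years = years, incidence = Fmid,
      lower = pmin(Flo, Fhi), upper = pmax(Flo, Fhi))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Proportional-hazards diagnostics (scaled Schoenfeld residuals)
#'
#' Score tests of the proportional-hazards assumption per term and
#' globally, using the identity time transform by default.
#'
#' @param fit a `cox_fit`.
#' @param transform time transform passed to `survival::cox.zph`.
#' @return data.frame `term`, `chisq`, `df`, `p_value` (last row GLOBAL).
#' @export
ph_diagnostics <- function(fit, transform = "identity") {
  if (fit$n_events < 1) stopf("no events")
  zp <- survival::cox.zph(fit$fit, transform = transform, global = TRUE)
  tab <- as.data.frame(zp$table)
  data.frame(term = rownames(tab), chisq = tab$chisq,
             df = tab$df, p_value = tab$p, row.names = NULL)
}
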