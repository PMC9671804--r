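# Phenome-wide logistic screen of overall average daily steps against every
# phecode, with Bonferroni familywise control.

#' Bonferroni-corrected significance threshold
#'
#' @param m number of tests actually performed (>= 1).
#' @return 0.05 / m.
#' @export
bonferroni_threshold <- function(m) {
  if (m < 1) stopf("m must be >= 1")
  0.05 / m
}

#' Phenome-wide logistic screen
#'
#' For each phecode, cases are persons whose first occurrence falls after
#' the washout window; persons with an occurrence before monitoring start or
#' within the washout are excluded for that phecode; controls never have an
#' occurrence (and have follow-up beyond the washout). Each phecode is fit
#' with a logistic regression of case status on overall average daily steps
#' adjusted for age, sex and race (complete-case), and the odds ratio is
#' reported per 1,000 step increase. Fits with fewer cases than
#' `min_events` are flagged unstable, not dropped; separation or fit
#' failure is flagged and the coefficient withheld.
#'
#' @param person_steps data.frame `person_id`, `mean_steps` (overall mean
#'   over valid days; see [person_mean_steps()]).
#' @param covariates data.frame with `person_id`, `age`, `sex`, `race`.
#' @param phecode_events output of [map_events_to_phecodes()].
#' @param monitoring data.frame `person_id`, `start_date`.
#' @param censoring data.frame `person_id`, `censor_date`.
#' @param washout_months washout length (default 6).
#' @param min_events minimum case count for a stable fit (default 20).
#' @param adjusters covariate columns for adjustment.
#' @return data.frame, one row per phecode: `phecode`, `n_cases`,
#'   `n_total`, `beta_per_step`, `or_1000`, `ci_low`, `ci_high`, `p_value`,
#'   `unstable`, `passes_bonferroni`, sorted by p; attributes `m_tests` and
#'   `alpha_bonferroni`.
#' @export
run_phewas <- function(person_steps, covariates, phecode_events, monitoring,
                       censoring, washout_months = 6, min_events = 20,
                       adjusters = c("age", "sex", "race")) {
  base <- merge(merge(person_steps, monitoring, by = "person_id"),
                censoring, by = "person_id")
  base <- merge(base, covariates[, c("person_id", adjusters)],
                by = "person_id")
  base$cens_m <- as.numeric(as.Date(base$censor_date) -
                              as.Date(base$start_date)) / 30
  phecodes <- sort(unique(phecode_events$phecode))
  rows <- vector("list", length(phecodes))
  for (i in seq_along(phecodes)) {
    pc <- phecodes[i]
    ev <- phecode_events[phecode_events$phecode == pc, ]
    occ_m <- (as.numeric(ev$first_date) -
                as.numeric(as.Date(base$start_date[
                  match(ev$person_id, base$person_id)]))) / 30
    stat <- rep(0L, nrow(base))               # control
    hit <- match(ev$person_id, base$person_id)
    keep_ev <- !is.na(hit)
    hit <- hit[keep_ev]; occ_m <- occ_m[keep_ev]
    stat[hit] <- ifelse(occ_m > washout_months, 1L, -1L)  # -1 = excluded
    d <- base[stat >= 0 & base$cens_m > washout_months, , drop = FALSE]
    d$case <- stat[stat >= 0 & base$cens_m > washout_months]
    d$steps_k <- d$mean_steps / 1000
    cc <- stats::complete.cases(d[, c("steps_k", adjusters)])
    d <- d[cc, , drop = FALSE]
    n_cases <- sum(d$case)
    out <- data.frame(phecode = pc, n_cases = n_cases, n_total = nrow(d),
                      beta_per_step = NA_real_, or_1000 = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_,
                      p_value = NA_real_,
                      unstable = n_cases < min_events,
                      stringsAsFactors = FALSE)
    if (n_cases >= 1 && n_cases < nrow(d)) {
      fml <- stats::as.formula(paste("case ~ steps_k +",
                                     paste(adjusters, collapse = " + ")))
      sep_flag <- FALSE
      g <- withCallingHandlers(
        tryCatch(stats::glm(fml, data = d, family = stats::binomial()),
                 error = function(e) NULL),
        warning = function(w) {
          if (grepl("fitted probabilities numerically 0 or 1",
                    conditionMessage(w))) sep_flag <<- TRUE
          invokeRestart("muffleWarning")
        })
      if (!is.null(g) && g$converged && !sep_flag) {
        sm <- summary(g)$coefficients
        b <- sm["steps_k", "Estimate"]; se <- sm["steps_k", "Std. Error"]
        out$beta_per_step <- b / 1000
        out$or_1000 <- exp(b)
        out$ci_low <- exp(b - 1.959964 * se)
        out$ci_high <- exp(b + 1.959964 * se)
        out$p_value <- sm["steps_k", "Pr(>|z|)"]
      } else {
        out$unstable <- TRUE
      }
    }
    rows[[i]] <- out
  }
  res <- do.call(rbind, rows)
  m <- sum(!is.na(res$p_value))
  alpha <- if (m >= 1) bonferroni_threshold(m) else NA_real_
  res$passes_bonferroni <- !is.na(res$p_value) & res$p_value < alpha
  res <- res[order(res$p_value), ]
  rownames(res) <- NULL
  attr(res, "m_tests") <- m
  attr(res, "alpha_bonferroni") <- alpha
  res
}
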