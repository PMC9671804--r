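# Multiple imputation by predictive mean matching and Rubin pooling.

# One PMM sweep for a single target column. Returns the column with missing
# entries replaced by donor values.
.pmm_column <- function(target, predictors, miss_idx, k_donors) {
  obs_idx <- which(!miss_idx)
  y <- target[obs_idx]
  is_cat <- is.factor(target) || is.character(target)
  yscore <- if (is_cat) as.numeric(factor(y)) else as.numeric(y)
  X <- stats::model.matrix(~ ., data = predictors)
  fit <- stats::lm.fit(X[obs_idx, , drop = FALSE], yscore)
  beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  pred <- drop(X %*% beta)
  p_obs <- pred[obs_idx]
  p_mis <- pred[miss_idx]
  filled <- target
  for (j in seq_along(p_mis)) {
    d <- abs(p_obs - p_mis[j])
    k <- min(k_donors, length(d))
    donors <- order(d)[seq_len(k)]
    pick <- donors[sample.int(k, 1)]
    filled[which(miss_idx)[j]] <- y[pick]
  }
  filled
}

#' Multiple imputation of missing covariates by predictive mean matching
#'
#' For each missing cell, a linear model (on score-coded values for
#' categorical columns) predicts the cell from the other covariates; the
#' imputed value is copied from one of the `k_donors` observed rows with the
#' nearest predicted mean, drawn uniformly. A single pass suffices when one
#' column is missing; otherwise chained sweeps (default 5) are run from a
#' random-draw initialisation. Every imputed value is an observed value of
#' its own column by construction.
#'
#' @param data covariate data.frame; columns listed in `exclude` (ids) are
#'   carried through untouched and not used as predictors.
#' @param m number of imputations (default 5).
#' @param k_donors donor pool size (default 5).
#' @param seed integer seed.
#' @param n_iter chained sweeps when more than one column is missing.
#' @param exclude columns to carry through unmodified.
#' @return object of class `imputation_set`: list with `imputations`
#'   (list of m completed data.frames), `m`, `k_donors`, `seed`,
#'   `missing_cols`.
#' @export
pmm_impute <- function(data, m = 5, k_donors = 5, seed = 1, n_iter = 5,
                       exclude = "person_id") {
  work_cols <- setdiff(names(data), exclude)
  na_count <- vapply(data[work_cols], function(c) sum(is.na(c)), numeric(1))
  miss_cols <- names(na_count[na_count > 0])
  if (any(na_count == nrow(data))) {
    stopf("column entirely missing: %s",
          paste(work_cols[na_count == nrow(data)], collapse = ", "))
  }
  if (length(miss_cols) == 0) {
    return(structure(list(imputations = replicate(m, data, simplify = FALSE),
                          m = m, k_donors = k_donors, seed = seed,
                          missing_cols = character(0)),
                     class = "imputation_set"))
  }
  iters <- if (length(miss_cols) == 1) 1 else n_iter
  miss_map <- lapply(data[miss_cols], is.na)
  imps <- lapply(seq_len(m), function(im) {
    with_seed(child_seed(seed, paste0("pmm", im)), {
      cur <- data
      for (v in miss_cols) { # random-draw initialisation
        obs <- cur[[v]][!miss_map[[v]]]
        cur[[v]][miss_map[[v]]] <- sample(obs, sum(miss_map[[v]]),
                                          replace = TRUE)
      }
      for (it in seq_len(iters)) {
        for (v in miss_cols) {
          preds <- setdiff(work_cols, v)
          pred_df <- cur[, preds, drop = FALSE]
          for (pv in names(pred_df)) {
            if (is.character(pred_df[[pv]]))
              pred_df[[pv]] <- factor(pred_df[[pv]])
          }
          # later columns in this sweep see the fresh draws via `cur`
          cur[[v]] <- .pmm_column(data[[v]], pred_df, miss_map[[v]],
                                  k_donors)
        }
      }
      cur
    })
  })
  structure(list(imputations = imps, m = m, k_donors = k_donors,
                 seed = seed, missing_cols = miss_cols),
            class = "imputation_set")
}

#' Pool estimates across imputations with Rubin's rules
#'
#' Qbar is the mean estimate, W the mean within-imputation variance, B the
#' between-imputation variance, and the total variance
#' T = W + (1 + 1/m) B. Degrees of freedom follow Barnard-Rubin when a
#' finite complete-data df is supplied, else the classic large-sample form.
#'
#' @param estimates numeric vector of per-imputation estimates (length m
#'   >= 2).
#' @param variances numeric vector of per-imputation squared standard
#'   errors.
#' @param dfcom complete-data degrees of freedom (default Inf).
#' @param conf confidence level.
#' @return list of class `pooled_estimate`: `q_bar`, `w_bar`, `b`, `t`,
#'   `se`, `df`, `ci_low`, `ci_high`, `p_value`, `m`.
#' @export
rubin_pool <- function(estimates, variances, dfcom = Inf, conf = 0.95) {
  m <- length(estimates)
  if (m < 2) stopf("need at least 2 imputations")
  if (length(variances) != m) stopf("mismatched lengths")
  qbar <- mean(estimates)
  w <- mean(variances)
  b <- stats::var(estimates)
  tt <- w + (1 + 1 / m) * b
  if (b > 0) {
    lambda <- (1 + 1 / m) * b / tt
    df_old <- (m - 1) / lambda^2
    if (is.finite(dfcom)) {
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
      df <- 1 / (1 / df_old + 1 / df_obs)
    } else {
      df <- df_old
    }
  } else {
    df <- Inf
  }
  se <- sqrt(tt)
  a <- 1 - (1 - conf) / 2
  q <- if (is.finite(df)) stats::qt(a, df) else stats::qnorm(a)
  p <- if (se > 0) {
    2 * (if (is.finite(df)) stats::pt(-abs(qbar / se), df)
         else stats::pnorm(-abs(qbar / se)))
  } else {
    NA_real_
  }
  structure(list(q_bar = qbar, w_bar = w, b = b, t = tt, se = se, df = df,
                 ci_low = qbar - q * se, ci_high = qbar + q * se,
                 p_value = p, m = m), class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "Pooled over %d imputations: %.4f (SE %.4f, 95%% CI %.4f to %.4f)\n",
    x$m, x$q_bar, x$se, x$ci_low, x$ci_high))
  cat(sprintf("W = %.5f, B = %.5f, T = %.5f, df = %.1f\n",
              x$w_bar, x$b, x$t, x$df))
  invisible(x)
}
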