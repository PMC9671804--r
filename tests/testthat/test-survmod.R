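# Spline basis, Cox fitting, AIC selection, chunk tests, contrasts,
# incidence curves and PH diagnostics.

test_that("rcs basis has k-1 columns, vanishing tails, linear extremes", {
  set.seed(301)
  x <- runif(500, 0, 100)
  kn3 <- c(10, 50, 90)
  b <- rcs_basis(x, kn3)
  expect_equal(ncol(b), 2)
  # below the first knot every nonlinear column is zero
  expect_true(all(b[x <= 10, 2] == 0))
  expect_error(rcs_basis(x, c(10, 10, 90)), "increasing")
  expect_error(rcs_basis(x, c(10, 90)), "3 knots")

  # linear beyond the last knot: second differences vanish
  for (k in 3:5) {
    kn <- rcs_knots(x, k)
    grid <- seq(max(kn) + 1, max(kn) + 30, by = 0.5)
    bb <- rcs_basis(grid, kn)
    f <- bb %*% runif(ncol(bb), -1, 1)
    d2 <- diff(diff(f))
    expect_lt(max(abs(d2)), 1e-8)
    # and below the first knot
    gl <- seq(min(kn) - 30, min(kn) - 1, by = 0.5)
    fl <- rcs_basis(gl, kn) %*% runif(ncol(bb), -1, 1)
    expect_lt(max(abs(diff(diff(fl)))), 1e-8)
  }
})

test_that("default knot placement follows the standard quantiles", {
  x <- 1:1000
  expect_equal(rcs_knots(x, 3), unname(quantile(x, c(.1, .5, .9))))
  expect_equal(rcs_knots(x, 5),
               unname(quantile(x, c(.05, .275, .5, .725, .95))))
  expect_error(rcs_knots(x, 6), "3, 4 or 5")
})

test_that("partial likelihood matches brute-force Efron enumeration on toys", {
  set.seed(302)
  for (i in 1:25) {
    toy <- fit_toy()
    cp <- toy$cp; f <- toy$fit
    bhat <- unname(f$coef[["steps"]])
    # null partial likelihood always comparable
    expect_lt(abs(f$fit$loglik[1] -
                    efron_loglik(0, cp$start, cp$stop, cp$event,
                                 cp$steps)), 1e-6)
    # interior optimum: maximised values and estimates agree; monotone
    # likelihoods (infinite beta) are skipped for the maximum comparison
    if (f$converged && abs(bhat) < 8) {
      expect_lt(abs(f$loglik -
                      efron_loglik(bhat, cp$start, cp$stop, cp$event,
                                   cp$steps)), 1e-6)
      opt <- optimize(function(b) efron_loglik(b, cp$start, cp$stop,
                                               cp$event, cp$steps),
                      interval = c(-15, 15), maximum = TRUE, tol = 1e-10)
      expect_lt(abs(bhat - opt$maximum), 1e-3)
      expect_lt(abs(f$loglik - opt$objective), 1e-6)
    }
  }
})

test_that("a null fit with distinct event times gives log risk-set sizes", {
  cp <- data.frame(person_id = letters[1:4], start = 0,
                   stop = c(1, 2, 3, 4), event = c(1, 1, 0, 1),
                   steps = c(1, 2, 3, 4))
  ll0 <- efron_loglik(0, cp$start, cp$stop, cp$event, cp$steps)
  expect_equal(ll0, -(log(4) + log(3) + log(1)))
})

test_that("AIC selection uses -2l + 2p with ties toward fewer knots", {
  mk <- function(ll, p, nev = 10) {
    structure(list(loglik = ll, aic = -2 * ll + 2 * p,
                   coef = rep(0, p), n_events = nev), class = "cox_fit")
  }
  expect_equal(mk(-100, 2)$aic, 204)
  sel <- select_by_aic(list(mk(-100, 2), mk(-100, 4)))
  expect_equal(length(sel$coef), 2)
  sel2 <- select_by_aic(list(mk(-100, 4), mk(-90, 5)))
  expect_equal(length(sel2$coef), 5)
  expect_error(select_by_aic(list(mk(-1, 2, nev = 5), mk(-1, 2, nev = 6))),
               "event counts")
})

# shared moderate simulation for the fit-level checks
sim_fit_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config(n_participants = 900, seed = 303,
                      hazard_spec = hazard_loglinear(0.80),
                      baseline_monthly_hazard = 0.004, n_null_phecodes = 0)
    sim <- simulate_study(cfg)
    pe <- map_events_to_phecodes(sim$conditions, sim$map)
    cens <- censoring_date(sim$encounters, sim$conditions)
    mon <- data.frame(person_id = sim$truth$person_id,
                      start_date = sim$truth$start_date)
    co <- build_incident_cohort(pe, mon, cens, "401.1")
    cp0 <- build_counting_process(co, monthly_exposures_all(sim$daily))
    cd <- sim$covariates_complete
    cp <- cbind(cp0, cd[match(cp0$person_id, cd$person_id),
                        c("age", "sex", "race", "bmi")])
    pms <- person_mean_steps(sim$daily)
    cache <<- list(cp = cp, sim = sim, co = co,
                   pms = pms[pms$person_id %in% co$cohort$person_id, ])
    cache
  }
})

test_that("chunk tests: 1-df equals squared Wald z; joint test behaves", {
  fx <- sim_fit_fixture()
  f <- fit_cox_tv(fx$cp, covariates = c("age", "sex", "race"))
  ct <- wald_chunk_test(f, "steps")
  z <- f$coef[["steps"]] / sqrt(f$vcov["steps", "steps"])
  expect_equal(ct$statistic, z^2)
  expect_equal(ct$df, 1)
  f3 <- fit_cox_tv(fx$cp, knots = 3, covariates = c("age", "sex", "race"))
  ct3 <- wald_chunk_test(f3, "exposure")
  expect_equal(ct3$df, 2)
  expect_gt(ct3$statistic, 0)
  expect_error(wald_chunk_test(f3, "nope"), "terms not in fit")
})

test_that("HR curve is anchored at the reference and matches closed forms", {
  fx <- sim_fit_fixture()
  f <- fit_cox_tv(fx$cp, covariates = c("age", "sex", "race"))
  ref <- median(fx$pms$mean_steps)
  hc <- hr_curve(f, c(ref, ref + 1000), ref)
  expect_equal(hc$hr[1], 1)
  expect_equal(hc$se[1], 0)
  # linear exposure: HR(ref+1000 vs ref) = exp(1000 * beta)
  expect_equal(hc$hr[2], exp(1000 * f$coef[["steps"]]))

  # spline curve equals pointwise linear-predictor differences
  f4 <- fit_cox_tv(fx$cp, knots = 4, covariates = c("age", "sex", "race"))
  grid <- seq(5000, 11000, by = 1500)
  hc4 <- hr_curve(f4, grid, ref)
  bs <- rcs_basis(c(grid, ref), f4$knots)
  lp <- bs %*% f4$coef[f4$exposure_terms]
  expect_equal(hc4$log_hr, as.numeric(lp[seq_along(grid)] -
                                        lp[length(grid) + 1]))
  expect_true(all(!hc4$extrapolated))
})

test_that("percentile contrast reproduces the closed-form linear case", {
  fx <- sim_fit_fixture()
  f <- fit_cox_tv(fx$cp, covariates = c("age", "sex", "race"))
  ct <- hr_contrast(f, s25 = 6000, s75 = 10580)
  expect_equal(ct$hr,
               exp(f$coef[["steps"]] * 4580))
  # with beta exactly ln(0.8)/1000 the contrast would be ~0.36
  expect_equal(exp(log(0.8) / 1000 * 4580), 0.36, tolerance = 0.01)
  # simulated contrast covers the generator truth
  ct2 <- hr_contrast(f, person_steps = fx$pms$mean_steps)
  truth <- fx$sim$ground_truth$true_hr_75_vs_25
  expect_true(ct2$lower <= truth * 1.15 && truth * 0.85 <= ct2$upper)
  expect_error(hr_contrast(f, s25 = 5, s75 = 5), "degenerate")
})

test_that("interaction contrasts use the profile BMI", {
  fx <- sim_fit_fixture()
  fi <- fit_cox_tv(fx$cp, covariates = c("age", "sex", "race", "bmi"),
                   bmi_interaction = TRUE)
  expect_true("bmi_x_steps" %in% names(fi$coef))
  ct <- hr_contrast(fi, s25 = 6000, s75 = 10000)
  bmi_ref <- fi$covariate_profile[["bmi"]]
  expect_equal(ct$log_hr,
               unname((fi$coef[["steps"]] +
                         bmi_ref * fi$coef[["bmi_x_steps"]]) * 4000))
})

test_that("cumulative incidence is monotone and tracks a constant hazard", {
  fx <- sim_fit_fixture()
  f <- fit_cox_tv(fx$cp, covariates = c("age", "sex", "race"))
  ci <- cumulative_incidence(f, c(6000, 8000, 10000), years = c(3, 5, 7))
  expect_true(all(ci$incidence >= 0 & ci$incidence <= 1))
  for (s in unique(ci$steps)) {
    expect_true(all(diff(ci$incidence[ci$steps == s]) >= 0))  # F(3)<=F(5)<=F(7)
  }
  # higher steps -> lower incidence under the protective truth
  expect_lt(ci$incidence[ci$steps == 10000 & ci$years == 5],
            ci$incidence[ci$steps == 6000 & ci$years == 5])

  # constant-hazard check: null exposure effect, known baseline
  set.seed(304)
  n <- 3000; lam <- 0.02
  tt <- rexp(n, lam); cmax <- 40
  cp <- data.frame(person_id = as.character(1:n), start = 0,
                   stop = pmin(tt, cmax), event = as.integer(tt <= cmax),
                   steps = rnorm(n))
  f0 <- fit_cox_tv(cp)
  ci0 <- cumulative_incidence(f0, s_values = 0, years = c(1, 2))
  expect_equal(ci0$incidence, 1 - exp(-lam * c(1, 2) * 365.25 / 30),
               tolerance = 0.03)
  expect_error(cumulative_incidence(f0, 0, years = 50), "beyond")
})

test_that("PH diagnostics return per-term and global score tests", {
  fx <- sim_fit_fixture()
  f <- fit_cox_tv(fx$cp, covariates = c("age", "sex", "race"))
  tab <- ph_diagnostics(f)
  expect_true("GLOBAL" %in% tab$term)
  expect_true(all(is.finite(tab$p_value)))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  # a proportional-hazards-true fit should not reject wildly
  expect_gt(tab$p_value[tab$term == "GLOBAL"], 1e-4)
})

test_that("Schoenfeld logic: single event residual is x minus risk-set mean", {
  cp <- data.frame(person_id = c("a", "b", "c"), start = 0, stop = c(2, 3, 4),
                   event = c(1, 0, 0), steps = c(1, 2, 4))
  f <- fit_cox_tv(cp)
  b <- f$coef[["steps"]]
  w <- exp(b * cp$steps)            # all three at risk at t = 2
  expected <- 1 - sum(cp$steps * w) / sum(w)
  got <- residuals(f$fit, type = "schoenfeld")
  expect_equal(unname(got[1]), expected, tolerance = 1e-8)
})

test_that("HR curve is invariant to affine recoding of covariates", {
  fx <- sim_fit_fixture()
  cp2 <- fx$cp
  cp2$age <- (cp2$age - 50) / 10
  f1 <- fit_cox_tv(fx$cp, knots = 3, covariates = c("age", "sex", "race"))
  f2 <- fit_cox_tv(cp2, knots = 3, covariates = c("age", "sex", "race"))
  hc1 <- hr_curve(f1, c(6000, 9000), 8000)
  hc2 <- hr_curve(f2, c(6000, 9000), 8000)
  expect_equal(hc1$hr, hc2$hr, tolerance = 1e-6)
  expect_equal(hc1$se, hc2$se, tolerance = 1e-5)
})
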