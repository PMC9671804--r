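---
title: "From wearable step streams to disease risk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From wearable step streams to disease risk: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepcourse)
```

## What the package models

`stepcourse` turns two longitudinal data streams — minute-level step counts
from a consumer wearable and diagnosis/encounter events from an electronic
health record (EHR) — into incident-disease analysis sets, and quantifies
how daily step volume relates to the hazard of developing chronic
conditions. The core statistical object is a time-varying Cox proportional
hazards model on a counting-process table: each participant contributes one
`(start, stop]` interval per monitored month, carrying that month's
exposure value, so the model

$$\lambda(t \mid s) = \lambda_0(t)\,\exp\{f(s(t)) + \gamma' z\}$$

uses the participant's evolving average daily step count $s(t)$ rather than
a single baseline snapshot. The exposure function $f$ is either linear or a
restricted cubic spline (RCS) with 3, 4 or 5 knots, the knot count chosen
by AIC; joint Wald "chunk" tests assess the overall association (all spline
terms) and nonlinearity (the nonlinear terms only). Effect sizes are
reported as hazard ratios at a grid of step values against the cohort
median, and as the contrast of the 75th versus the 25th percentile of
person-level mean daily steps. A phenome-wide logistic screen
(odds ratio per 1,000 steps, Bonferroni-controlled) provides the
hypothesis-generating front end, and cumulative incidence at fixed step
levels is derived from the Breslow baseline hazard.

## Wearable processing rules

All constants are exposed as arguments with these defaults:

* **Valid day**: at least 10 wear hours and at least 100 steps. Wear time
  is the number of clock hours (00–23) containing a non-zero minute —
  clock-hour buckets, not sliding windows, being the plainest reading of
  "hours in a day". Days under 100 steps are removed before any other
  computation.
* **Cadence bouts**: maximal runs of ≥ 2 consecutive minutes at ≥ 60
  steps/min (slow walking) or ≥ 100 steps/min (moderate-to-vigorous).
  Bout cadence is pooled as total bout steps over total bout minutes —
  time-weighted, not a mean of per-bout means — so long bouts count
  proportionally to their duration.
* **Months** are consecutive 30-day blocks from each participant's first
  monitored day. Calendar months would be arbitrary after the
  privacy-motivated date shifting such datasets undergo; 30-day blocks are
  translation-invariant. A month is valid with ≥ 15 valid days.
* **Inclusion** requires ≥ 6 months between first and last valid day.

## Exposure timing and information leakage

The time-varying exposure attached to the interval `(m, m+1]` is computed
from data **strictly before month m**: by default the running mean of all
valid days through month `m−1` (`exposure_mode = "running"`), or month
`m−1`'s own mean (`"month"`). A non-event interval is retained only when
month `m−1` is valid, so invalid months open gaps in the risk set; the
event interval is always retained with the most recent available exposure,
because the diagnosis itself is observed in the EHR regardless of device
wear. This one-month lag is deliberately stricter than attaching the
concurrent month's average: it guarantees — and the test suite verifies —
that perturbing any step data on or after the event month leaves the
counting-process table bit-for-bit unchanged. With a running mean the lag
costs almost nothing (consecutive running means differ little), and it
removes any route for outcome-adjacent behaviour change to contaminate the
exposure.

Cohort entry starts at the end of a 6-month washout: diagnoses coded in the
first 6 months are treated as prevalent-but-unrecognised and exclude the
participant for that outcome, as do diagnoses before monitoring. Risk time
before the washout end is never counted (late entry at month 6, not entry
at time 0), since a person who would have been excluded had they been
diagnosed earlier cannot logically contribute earlier risk time. Censoring
is the last medical encounter across measurement, laboratory, procedure and
condition records.

## Splines, contrasts and intervals

The RCS basis uses the truncated-power parameterisation (k knots → k−1
columns, linear tails beyond the boundary knots, scaled by
$(t_k - t_1)^2$), with knots at the standard quantiles of the pooled
person-month exposure distribution (0.10/0.50/0.90 for 3 knots;
0.05/0.35/0.65/0.95 for 4; 0.05/0.275/0.50/0.725/0.95 for 5) — the
modelling scale is the person-month, so that is where the knots live. Ties
are handled by Efron's method (Breslow available by flag). All curve and
contrast intervals are delta-method Wald intervals on the linear-predictor
contrast; the hazard ratio at the reference is exactly 1 with a degenerate
interval. Cumulative incidence holds covariates at a reference profile
(median continuous values, modal categories — the choice is explicit
because no single convention exists) and reports
$F(t\mid s) = 1 - \exp\{-\hat\Lambda_0(t)e^{\hat{lp}(s)}\}$; its interval
propagates only the linear-predictor uncertainty, not baseline-hazard
uncertainty, and since entry begins at washout end it is incidence
conditional on being event-free at entry. Proportional hazards are checked
with score tests on scaled Schoenfeld residuals; the identity time
transform is the default because the analysis clock (months) is already the
scale on which exposure varies.

The adjustment suite follows the conventional layering: Model 1 = steps
(time-varying) + age, race, sex; Model 2 adds systolic blood pressure, CAD,
cancer, smoking, education, alcohol and BMI; Model 3 adds time-varying wear
hours; Models 4 and 5 add baseline steps averaged over the first 3 and 6
months (reverse-causation probes). An interaction variant lets BMI modify
the step effect linearly, and an intensity-adjusted variant enters bout
cadence as a second spline. When models are fitted across multiple
imputations, the spline knot count is selected once by the *summed* AIC
across completed datasets (a single model form must apply to all
imputations for Rubin pooling to be meaningful), percentile-contrast log
hazard ratios are pooled with Rubin's rules, and chunk-test p-values are
summarised by their median across imputations — a pragmatic summary, since
exact chunk-test pooling under multiple imputation has no closed form.

## Multiple imputation

Missing covariates are imputed by predictive mean matching: a linear model
predicts each incomplete column from the others, and every missing cell
receives the observed value of one of the 5 donors with the nearest
predicted mean, drawn uniformly. Categorical columns are score-coded for
prediction; the donor-copy step keeps every imputed value in-domain. With
one incomplete column a single pass is exact; otherwise five chained sweeps
are run from a random-draw initialisation. This is a deliberate,
documented simplification of full additive-model imputation machinery: it
preserves the two properties the pipeline relies on (imputed values are
observed donor values; non-missing cells are invariant across
imputations), and the test suite verifies that pooled Cox estimates on
MCAR-degraded covariates remain unbiased. Pooling uses Rubin's rules
($\bar Q$, $\bar W$, $B$, $T = \bar W + (1+1/m)B$) with Barnard–Rubin
degrees of freedom when a finite complete-data df is supplied.

## The synthetic cohort generator

The generator exists so that every downstream stage is exercisable, with
known ground truth, on data that never leaves the machine. Its defaults are
the study conditions the pipeline targets:

* person-level mean daily steps log-normal with median 7,731 steps/day and
  log-SD 0.38 (reproducing an IQR of roughly 5,870–9,830);
* monitoring duration uniform on 0.5–7.5 years (median 4.0, IQR ≈ 2.3–5.7);
* mean wear 14 h/day (SD 2) on worn days; per-person-month wear propensity
  Beta-distributed with mean 0.80 and precision 1.5, which makes non-wear
  *clustered* and yields an expected ~15% of months with fewer than 15
  valid days (`expected_invalid_month_rate()` gives the closed form);
* day-to-day step totals log-normal around the person level with log-SD
  0.35 — the day-level variance is **not** reported in the literature this
  emulates, so this value is a documented choice, not a calibration;
* bout cadence centred at 85 steps/min (slow walking) with a
  moderate-to-vigorous subset near 110, and person-level cadence coupled to
  step volume (coupling 0.65, giving Spearman ρ ≈ 0.6 between volume and
  intensity, inside the 0.48–0.87 range reported for free-living cohorts);
* covariate missingness MCAR at per-covariate rates matching the reference
  cohort (BMI 43.8%, race 5.4%, …) — MCAR by design, so that predictive
  mean matching can be validated without conflating it with
  missingness-mechanism misspecification.

Disease events are drawn by inverse-transform sampling on a
piecewise-constant monthly hazard
$\lambda_m = \lambda_0 \exp\{lp(s_m)\}$, where $s_m$ is the **true**
running-average daily step count entering month $m$ — the same quantity,
up to valid-day sampling noise, that the analysis model reconstructs. Three
hazard shapes are available: `hazard_null()` (events independent of steps,
for falsification and familywise calibration), `hazard_loglinear()`
(constant HR per 1,000 steps), and `hazard_plateau()` (log-linear below a
knot, flat above it, emulating risk curves that stop improving above
~8,000–9,000 steps/day). The default baseline hazard of 0.0025/month
produces event fractions comparable to the reference cohort's outcome
counts. Covariates carry no hazard effect by default: the adjusted model
remains consistent, and the ground-truth contrast
$\exp\{lp(s_{75}) - lp(s_{25})\}$ stays exact. Prevalent and washout-window
occurrences, a second outcome coded under two combinable phecodes,
step-independent null phecodes, and deliberately unmapped codes are all
emitted so that mapping, combination, exclusion and logging paths run on
every simulation.

Two generation paths share one schema: `gen_daily_series()` draws daily
summaries directly (fast; used for cohort-scale simulation), while
`gen_minute_stream()` materialises full 1,440-slot minute vectors whose
re-aggregation through `summarize_days()` reproduces the generator's
internal daily totals exactly — the bookkeeping identity the tests pin
down. An optional uniform date shift mimics the privacy transform of the
real data and, by construction and by test, changes no
monitoring-relative estimate.

What the generator does **not** emulate: circadian structure within the
day, device-model heterogeneity, seasonal and pandemic-era effects,
informative (activity-dependent) missingness, and hazard effects of the
adjustment covariates. Passing recovery tests on this generator therefore
demonstrates that the pipeline's machinery is correct and unbiased under
its stated assumptions — not that those assumptions hold in any particular
real cohort.

## Simulation evidence the package ships with

The test suite recomputes, at every run: oracle equivalence of bout
detection, wear-time counting and the Efron partial likelihood against
brute-force enumerations; recovery of a true HR of 0.80 per 1,000 steps at
n = 2,000 over 20 replicates (bias ≤ 0.05 on the log scale, interval
coverage within 85–100%); detection of plateau-shaped nonlinearity by
chunk tests and AIC knot selection (plateau at 8,000 steps/day, 20
replicates) against near-nominal false-positive rates under a log-linear
truth; uniformity of falsification p-values over 50 step-independent
replicates; exact washout/censoring/gap arithmetic on constructed
fixtures; and closed-form Rubin pooling. Problem sizes (n = 500–2,000, 20–50
replicates) were chosen so the full suite completes in well under half an
hour on a single core while keeping Monte-Carlo error far below the
tolerances being asserted.

## Known limitations

* The logistic screen uses complete cases for its adjusters; imputation is
  reserved for the Cox stage, mirroring common practice.
* Chunk-test p-values across imputations are summarised by the median
  rather than a formal combination rule.
* Cumulative-incidence intervals ignore baseline-hazard uncertainty.
* The exposure lag makes "month-mode" exposures one month older than a
  concurrent-month analysis would use; with running means the difference
  is negligible, and the default is the running mean.
* PMM here is single-model matching, not the full bootstrap/flexible-basis
  imputation found in dedicated imputation packages.
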