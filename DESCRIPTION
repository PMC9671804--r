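Package: stepcourse
Title: Wearable Step Counts, Incident Disease Cohorts, and Time-Varying
    Survival Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to transform minute-level wearable step streams and
    electronic-health-record diagnosis streams into incident-disease
    analysis sets, and to quantify step-count/disease-risk relationships.
    Includes valid-day and wear-time processing, cadence-bout detection,
    monthly time-varying exposure construction, ICD-to-phecode mapping
    with washout-based incident cohort definitions, a phenome-wide
    logistic screen with Bonferroni control, time-varying Cox models with
    restricted cubic splines (AIC knot selection, chunk tests, hazard
    ratio curves, percentile contrasts, cumulative incidence, proportional
    hazards diagnostics), multiple imputation by predictive mean matching
    with Rubin pooling, and a synthetic cohort generator with known
    ground-truth hazard-step relationships so the whole pipeline is
    testable without access-controlled data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
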