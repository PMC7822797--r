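Package: facdid
Title: Facility-Level Difference-in-Differences with Kernel Propensity-Score Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates health-facility accreditation programs on a facility-by-wave
    panel built from individual survey records. Links survey respondents to their
    nearest facility by great-circle distance, collapses binary health outcomes into
    facility-level percentages, and estimates treatment effects with a fixed-effects
    difference-in-differences model, a two-period covariate-adjusted
    difference-in-differences model, and a kernel propensity-score-matching
    difference-in-differences estimator, all with cluster-robust or bootstrap
    inference. Ships a synthetic-data generator with known ground-truth effects,
    vulnerability-index-driven targeting and staggered rollout, plus common-support,
    covariate-balance, parallel-trends and placebo diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
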