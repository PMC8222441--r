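Package: pedtriage
Title: Five-Level Pediatric Emergency Triage Classification and Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a five-level rule-based pediatric emergency department
    triage algorithm combining a Pediatric Assessment Triangle gate,
    life-saving-intervention and high-risk screens, age-banded vital-sign
    reference ranges, and predicted resource counts, together with the
    validation machinery used to evaluate such instruments: over-/under-triage
    adjudication from encounter outcomes, screening performance metrics
    (sensitivity, specificity, predictive values with exact binomial
    confidence intervals), contingency-table odds ratios with Woolf
    log-normal intervals, and a deterministic synthetic cohort generator so
    the whole pipeline is reproducible without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
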