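Package: aaadecide
Title: Dynamic Rupture Risk and Optimal Intervention Timing for
    Abdominal Aortic Aneurysm Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint modelling of longitudinal abdominal aortic aneurysm
    (AAA) diameter measurements and rupture risk, with tools to turn the
    fitted model into personalised surveillance decisions. Fits a shared
    random-effects joint model (linear mixed-effects growth trajectory
    linked to a proportional-hazards rupture sub-model) by maximum
    likelihood using adaptive Gauss-Hermite quadrature, computes dynamic
    conditional rupture probabilities that update as ultrasound
    measurements accrue, and embeds those predictions in an
    expected-life-years decision model that balances rupture risk against
    elective operative mortality to return an optimal (and dynamically
    updatable) time of elective repair. Includes a synthetic screening
    cohort simulator, time-dependent AUC / dynamic discrimination
    summaries, and CSV import/export for cohort, life-table and decision
    artefacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    pracma,
    lme4,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
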