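Package: sepsiscreen
Title: Prehospital Sepsis Screening Scores on Synthetic EMS Cohorts
Version: 0.1.0
Authors@R:
    person("EMS Analytics", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate prehospital sepsis screening instruments
    (qSOFA, SIRS, MEWS, NEWS2, each adapted to the variables available to
    emergency medical services) against an inpatient sepsis label. Includes
    a synthetic EMS cohort generator with configurable documentation rates,
    implausible-value contamination and mortality follow-up; two-slot vital
    sign resolution with plausibility filtering and selectable missing-data
    strategies (complete case, missing-as-normal, stratified hot-deck,
    missing-as-worst); diagnostic accuracy statistics with Wilson
    confidence intervals, McNemar and Pearson chi-squared tests; screening
    tool set-intersection analysis; and cohort epidemiology reports
    (incidence, case fatality, documentation completeness, suspicion
    rates), orchestrated by a scriptable pipeline with a CSV/JSON
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
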