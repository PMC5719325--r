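Package: tiaflow
Title: Discrete Event Simulation of Specialist TIA Service Provision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating specialist transient ischaemic attack (TIA)
    outpatient services as a discrete event model. Synthetic referral streams
    with ABCD2-based risk stratification flow from symptom onset through
    GP or emergency-department presentation into capacity-constrained clinic
    calendars under configurable allocation policies (priority queueing,
    reserved and on-demand slots, admit-if-breach, timed ward review).
    Subsequent major-stroke risk is modelled with a two-anchor calibrated
    Weibull hazard modified by covariates and treatment timing. Batch runners
    aggregate costs, guideline-breach counts, waiting times and stroke
    incidence with 99% quasi-confidence intervals, including weekend-service
    variants and high:low risk-mix sensitivity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
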