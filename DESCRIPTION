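Package: abpsim
Title: Budget Impact Simulation of Annuity-Based Payments for Advanced
    Therapies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic budget-impact simulation comparing upfront
    lump-sum payment with annuity-based payment (ABP) schemes for one-time
    advanced therapies over a multi-year horizon. Builds yearly treated-patient
    flows from disease epidemiology (prevalent backlog plus growing incident
    cohorts), prices annuity-due repayment schedules at a bond rate, constructs
    nominal and discounted payer cashflow streams, and screens four feasibility
    conditions for managed entry agreements: budget-cap exceedance, net present
    value cost-equivalence, maximum-yearly-budget non-exceedance, manufacturer
    risk compensation, and a durability-limited annuity count. Ships
    prevalence-dominant and incidence-dominant disease presets, parameter
    sweeps over the feasibility space, YAML scenario configuration, tabular
    report export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
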