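Package: trialcea
Title: Trial-Based Cost-Effectiveness Analysis with Bootstrap Uncertainty
Version: 0.1.0
Authors@R:
    person("trialcea", "maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for trial-based economic evaluation of
    two-arm mental-health service trials: scoring of PHQ-9 and WHODAS-12
    instruments, mapping of WHODAS items and sociodemographics to a
    preference-weighted disability index, quality-adjusted life years by
    area under the health-status curve, implementation and service-delivery
    costing in international dollars, multiple imputation by chained
    equations with predictive mean matching, incremental cost-effectiveness
    ratios under program-total and per-participant approaches, nonparametric
    paired bootstrap confidence intervals, willingness-to-pay threshold
    fractions, and cost-effectiveness acceptability curves. Includes a
    synthetic two-arm trial generator with analytic ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
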