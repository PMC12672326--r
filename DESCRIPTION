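Package: pcsk9cua
Title: Cost-Utility Modelling of PCSK9 Inhibitor Regimens Added to Statins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A Markov cohort state-transition model for cost-utility analysis
    of PCSK9 inhibitor dosing regimens added to statin therapy in a
    hypercholesterolemia cohort. Translates absolute LDL-C reductions into
    cardiovascular event-rate reductions via per-mmol/L rate ratios, runs an
    11-state cohort trace with tunnel states for the first post-event year,
    and computes discounted lifetime costs and QALYs with half-cycle
    correction. Provides incremental cost-utility ratios with dominance and
    extended-dominance frontier analysis, one-way (tornado) sensitivity
    analysis, probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, time-horizon scenario analysis, and value-based
    price-threshold analysis, together with a synthetic Gompertz-Makeham
    life-table generator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
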