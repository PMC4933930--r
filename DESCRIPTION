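Package: niptscreen
Title: Cost-Consequence Modelling of Contingent Non-Invasive Prenatal
    Testing in a National Down's Syndrome Screening Programme
Version: 0.1.0
Authors@R:
    person("Screening", "Economics Group", , "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decision-tree evaluation of adding non-invasive prenatal
    testing (NIPT) as a contingent second-line test to a national Down's
    syndrome screening programme. Implements seven testing strategies
    (current pathway; contingent NIPT at risk thresholds 1/150, 1/500 and
    1/1000, each with or without a direct invasive-testing option),
    deterministic national-scale cost and outcome projection,
    probabilistic sensitivity analysis with beta/gamma/Dirichlet input
    distributions, one-way threshold and cost-neutral price analyses,
    uptake scenario tables, and an individual-level synthetic cohort
    generator with parameter re-estimation and exact binomial
    (Clopper-Pearson) diagnostic accuracy statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
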