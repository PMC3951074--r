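Package: protonCEA
Title: Cost-Utility Analysis of Proton Versus X-Ray Radiotherapy for
    Childhood Medulloblastoma
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Lifetime three-state Markov cohort model comparing proton beam
    therapy with conventional X-ray radiotherapy for 6-year-old
    medulloblastoma patients, where the clinical benefit of protons is a
    reduced cochlear dose and hence a lower risk of severe (Grade 3-4)
    hearing loss.  Computes discounted lifetime costs and quality-adjusted
    life years under the EQ-5D, HUI3 and SF-6D utility indexes, incremental
    cost-effectiveness ratios, one-way (tornado) sensitivity analyses,
    probabilistic sensitivity analysis with triangular parameter
    distributions, and cost-effectiveness acceptability curves.  Includes a
    calibrated logistic cochlear dose-response tool for scenario analyses
    and a Gompertz-Makeham life-table generator supplying background
    mortality.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
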