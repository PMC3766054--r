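Package: redoxferm
Title: Redox-Balance Scenario Modelling of Anaerobic Yeast Fermentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stoichiometric scenario modelling of anaerobic Saccharomyces
    cerevisiae fermentation with and without a phosphoribulokinase/Rubisco
    CO2-fixation route that replaces glycerol formation as the sink for excess
    biosynthetic NADH. Provides a lumped carbon/NADH/NADPH/ATP-balanced network
    solver, calibration of its stoichiometric coefficients to observed chemostat
    yields, yield predictions and global production projections, an analysis
    pipeline for chemostat and batch fermentation records (ethanol-evaporation
    correction, molar yields, gas balances, carbon and electron recovery, strain
    comparison, growth-rate fitting, enzyme-assay censoring), and a synthetic
    fermentation data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
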