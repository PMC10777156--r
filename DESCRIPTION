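Package: peatstab
Title: Stability of Peat-Moss Mesocosm CO2 Exchange Under Water Table Drawdown
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for replacement-series peat-moss
    mesocosm drought experiments. Generates synthetic net ecosystem CO2
    exchange (NEE) series and raw closed-chamber CO2 concentration traces,
    computes NEE from chamber traces by dead-band trimmed linear regression
    and ideal-gas conversion, derives per-mesocosm stability statistics
    (signed resistance, resilience, drawdown response slopes, recovery
    rates), and produces group-level slope tables, one-way ANOVA and Tukey
    HSD contrasts across Sphagnum mixture compositions and drawdown
    treatments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
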