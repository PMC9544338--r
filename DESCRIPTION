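Package: gokinetics
Title: Kinetic Modelling and Screening Analytics for Fluorescent GTPase Assays
Version: 0.1.0
Authors@R:
    person("Plate", "Kinetics Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward kinetic models and nonlinear least-squares fitters for
    plate-reader fluorescence assays of heterotrimeric G-protein alpha subunits
    (BODIPY-GTP/GTPgammaS uptake, hydrolysis and displacement), yielding the
    observed binding (k_bind), hydrolysis (k_hydr) and dissociation (k_diss)
    rate constants with standard errors and fold-change comparisons.
    Includes the statistics of a DMSO-referenced high-throughput drug screen
    (z-distance hit calling on k_bind and maximal GTP uptake), one-way ANOVA
    dose-dependence analysis for rescue series, quantification of BRET
    heterotrimer-dissociation time series (basal and plateau ratios), seeded
    synthetic-data generators emulating every input, and a small command-line
    interface binding the pieces into reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
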