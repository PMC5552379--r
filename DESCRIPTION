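Package: isobolr
Title: Fixed-Ratio Isobolographic Analysis of Drug Combinations
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for fixed-ratio isobolographic analysis of drug-combination
    antinociception experiments: ordinary least-squares regression of percent
    maximum possible effect (%MPE) on log10 dose, effective-dose (ED20)
    estimation with delta-method log-scale variance, variance-weighted
    fixed-ratio mixture design with geometric dose ladders, comparison of the
    experimental mixture ED20 against the Loewe-additive prediction by a
    composite t-test, interaction-index and isobologram computation, and a
    synthetic-data generator with known ground truth for validating every
    stage.  Ships curated per-animal dose-effect tables for a TRPV1
    antagonist (SB366791) and a voltage-gated calcium channel blocker toxin
    (Phalpha1beta) in the mouse capsaicin test, alone and in combination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
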