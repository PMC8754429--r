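Package: coldcomp
Title: Rate and Stability Compensation Analysis of Enzyme Temperature
    Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing the rate-compensation model of enzyme cold
    adaptation from literature kinetic data. Curates enzyme kinetic constants
    (kcat, kcat/KM) matched to organismal optimal growth temperature, computes
    per-reaction cold/warm rate ratios together with a same-growth-temperature
    control null distribution, compares the two by a Mann-Whitney U test with
    bootstrap confidence intervals on medians, screens per-reaction
    log10(rate) versus growth-temperature slopes with Bonferroni correction,
    and mirrors the analysis for protein melting temperatures. Includes a
    Michaelis-Menten fitter for initial-rate series and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
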