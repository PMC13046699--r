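Package: isobolr
Title: Isobolographic Analysis of Fixed-Ratio Drug Combinations from MTT Plate Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end Loewe-additivity isobolographic analysis of two-drug,
    fixed-ratio cytostatic combinations assayed by MTT viability plates:
    normalization of raw optical densities to percent inhibition, log-probit
    concentration-response fitting with IC50 and delta-method standard errors,
    a slope parallelism test, theoretical additive IC50 predictions (a single
    point for parallel curves, lower/upper bounds for nonparallel ones),
    Welch-corrected comparison of the experimental mixture IC50 against the
    additive prediction, synergy/antagonism classification, and polygonogram
    and summary-matrix reporting. Includes a seeded synthetic-plate generator
    with a controllable interaction parameter for validation by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
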