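Package: dosecomp
Title: Gene Dosage-Compensation Analysis from Sequencing Depth Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects whole-chromosome aneuploidy from relative sequencing
    depth, classifies amplified genes into dosage-response classes both in
    aneuploid-euploid strain pairs (chromosome-calibrated gene-specific
    cutoffs) and across isogenic dosage panels (a constrained random-effects
    mixture of linear regressions fit by EM), detects unamplified
    trans-responding genes with FDR control, and scores genes for buffering
    of copy-number variation by combining amplification frequency across
    natural isolates with the expression-constraint ratio Vg/Vm. Includes a
    synthetic-data module that simulates strain-panel read counts, aCGH
    matrices, and variance tables with known ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stats,
    utils,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
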