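Package: huntdiv
Title: Prey Division and Attack-Order Analysis for Group-Hunting Predators
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of time-stamped attack event logs from group hunts of
    individually identified predators that take turns attacking a shared
    prey school. Provides the core event-sequence toolkit: derivation of
    dash sequences (maximal runs of consecutive attacks by one individual),
    segmentation of the appearance order into arrival subgroups by a
    normalized gap statistic, an equal-access multinomial null model with
    Monte-Carlo percentile bands, constrained permutation tests for
    inter-individual differences in dash-sequence length and for
    turn-interruption (ABA) patterns in the attack order, prey-division
    summaries (cumulative capture-share curves, uniformity and rank
    correlation tests, Monte-Carlo capture-efficiency tests), length-weight
    allometry from calibrated still-frame measurements, and a synthetic
    hunt generator with known ground truth for calibration and power
    studies.
License: MIT
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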