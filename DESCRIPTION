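Package: pehm
Title: Pentamer Region-Dependent Hybridization Model for Microarray Probe Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-based prediction of oligonucleotide probe-target
    hybridization affinity in the presence of mismatches and gaps, for the
    design of microarrays targeting repetitive elements such as human
    endogenous retroviruses (HERVs). Implements the pentamer
    region-dependent hybridization model in which probe intensity is the
    product of target abundance and a sequence-determined affinity, the
    affinity being a sparse (LASSO-penalized) sum of region-tagged pentamer
    effects with mismatch and gap tokens and mismatch-interaction terms.
    Includes hybridization-threshold calibration, a three-step probe and
    probeset design pipeline with cross-hybridization control (tiling,
    affinity/specificity filtering, probeset assembly), titration-based
    platform evaluation statistics (monotonic titration response, mixture
    fraction estimation, replicate coefficients of variation, background
    estimators, differential-expression filtering), and seed-deterministic
    synthetic-data generators for degenerate probe training sets, titration
    designs and repetitive sequence families.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    Matrix,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
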