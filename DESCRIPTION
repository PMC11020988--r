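Package: petromics
Title: First-Order FDG PET Radiomics, Reference-Organ Uptake and Outcome Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing FDG PET volumes in oncology cohorts: adaptive-threshold
    tumor delineation (Nestle method), the ten first-order and SUV-intensity-histogram
    tumor features (maximum/mean/median SUV, MTV, TLG, CoV, kurtosis, skewness, entropy,
    uniformity), bone-marrow/liver/spleen reference uptake with BLR and SLR ratios, and
    the downstream statistics linking imaging features to ordinal immunohistochemical
    grades and recurrence-free survival (Kruskal-Wallis with Dunn post-hoc, Mann-Whitney,
    Cox proportional hazards, ROC cutoff selection, Kaplan-Meier with log-rank, and
    stage-by-imaging recurrence stratification). Includes generators for synthetic PET
    phantoms with known ground truth and for synthetic cohorts with a controllable
    feature-grade-hazard structure, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    survival,
    RNifti,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
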