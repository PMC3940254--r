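Package: xenomark
Title: Quantification and Tumor-Line Classification of Xenograft IHC and PET Data
Version: 0.1.0
Authors@R: person("Maarten", "Vos", email = "m.vos@example.org", role = c("aut", "cre"))
Description: Tools for systematic characterization of tumor xenograft lines from
    immunohistochemistry (IHC) marker images and small-animal PET uptake volumes.
    Quantifies staining fractions, labeling index, vascular density, perfused
    fraction, SUV statistics with 40 percent SUVmax auto-delineation, and global
    first-order texture features (mean, skewness, Shannon entropy) after fixed
    bin-width discretization. Decomposes each parameter into within- and
    between-line variance with a one-way random-intercept model, and evaluates
    Random Forest tumor-line classifiers under a shared-split repeated
    cross-validation design with paired model comparison, permutation importance
    and an exhaustive parameter-subset sweep. Includes synthetic cohort, image
    and volume phantom generators with exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
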