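Package: tspopet
Title: Quantification of TSPO PET Neuroinflammation Imaging with
    Metabolite-Corrected Input Functions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for quantifying translocator protein
    (TSPO) overexpression, a marker of brain inflammation, from dynamic
    small-animal PET studies with arterial blood sampling. Implements
    decay correction and weight normalisation of gamma-counted blood
    samples, two-exponential parent-fraction (metabolite) standard curves
    with between-group comparison of fits, metabolite-corrected plasma
    input functions, the one-tissue compartment model with a fixed
    vascular fraction for estimating the tracer volume of distribution
    (Vt), the simplified late-time tissue-to-plasma ratio (r50'),
    densitometric calibration of film autoradiograms against co-exposed
    standards with specific-binding computation, and the group statistics
    used in such studies (Welch-corrected t tests, one-way ANOVA with
    Tukey post hoc tests, Pearson correlation, percent difference). A
    synthetic-cohort simulator with known ground-truth kinetics makes
    every stage testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    deSolve,
    RNifti,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
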