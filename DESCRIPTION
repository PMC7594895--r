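Package: petharm
Title: Harmonisation of PET SUV Measurements Across Scanners by Gaussian
    Resolution Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for harmonising standardised uptake values (SUV) between
    PET/CT scanners of different effective resolution. Simulates NEMA IEC
    body-phantom acquisitions on virtual scanners (Gaussian point-spread
    blur, optional resolution-recovery edge overshoot, grid resampling,
    replicate noise), measures per-sphere recovery coefficients, derives the
    Gaussian harmonisation kernel width that brings a scanner or protocol
    inside an EARL-style recovery-coefficient acceptance window or inside a
    window transferred from a second scanner, applies the kernel to lesion
    SUVmax, and evaluates the effect with the usual statistical battery
    (Shapiro-Wilk gated log10 transform, one-way ANOVA, Wilcoxon signed
    rank, ratio Bland-Altman, ordinary least squares).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
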