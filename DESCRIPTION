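Package: vmre
Title: Virtual MR Elastography from Diffusion-Weighted MRI: Simulation,
    Mapping and Diagnostic Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates diffusion-weighted MRI phantoms and liver-fibrosis
    patient cohorts, computes shifted apparent diffusion coefficient (sADC)
    and virtual MR elastography (VMRE) stiffness maps from paired b-value
    volumes, aggregates maps over regions of interest with elastography
    quality control, stages fibrosis against fixed MR elastography
    thresholds (METAVIR F0-F4), and evaluates diagnostic performance with
    ROC/Youden analysis, intraclass correlation, Bland-Altman agreement,
    Kruskal-Wallis with Dunn post hoc tests, one-way ANOVA and normality
    screening. An end-to-end pipeline reproduces the full analysis on
    synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    png,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    nortest,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
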