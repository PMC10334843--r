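Package: adipoflim
Title: Label-Free Optical Metabolic Imaging Analysis of Adipose Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for label-free two-photon
    metabolic imaging of adipose tissue. Generates synthetic cohorts, tissue
    scenes, multi-channel NAD(P)H/FAD/lipofuscin image stacks and TCSPC photon
    decay frames with known ground truth; segments macrophages by their
    lipofuscin-like red autofluorescence and adipocyte cytoplasm rims by
    NAD(P)H+FAD signal; detects crown-like structures; computes optical redox
    ratios and bi-exponential NAD(P)H fluorescence lifetimes by IRF-convolved
    fitting; quantifies channel colocalization (Pearson and Manders
    coefficients, line profiles); and provides the multivariate diagnostic
    layer (Z-score readout tables, logistic regression with leave-one-out
    cross-validation, ROC/AUC/Youden analysis, PCA, group tests, HOMA-IR and
    bioenergetic metric arithmetic).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    jsonlite,
    pracma,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    tiff,
    png,
    withr,
    optparse
Config/testthat/edition: 3
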