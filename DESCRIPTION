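Package: phoxcell
Title: Analysis of Acidosis-Hypoxia Cell Culture Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how extracellular pH and oxygen interact in
    cultured cells. Fits biphasic Hill-type pH-survival curves to growth plates,
    converts ratiometric pH-probe and oxygen-probe plate-reader traces into
    cumulative acid production and oxygen consumption, detects and classifies
    lysosomal puncta in fluorescence images with a circular Hough transform and
    a trained radius-intensity classifier, analyses factorial (pH x O2)
    label-free proteomics with left-censored imputation, and computes qPCR
    delta-delta-Ct fold changes and proteasome activity readouts. Seeded
    synthetic-data generators provide ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    MASS,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
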