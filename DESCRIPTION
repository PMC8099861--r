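Package: riliquant
Title: Quantitative Imaging and Histology Pipeline for Radiation-Induced
    Lung Injury Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reusable analysis pipeline for longitudinal large-animal
    studies of radiation-induced lung injury. Computes first-order and
    grey-level co-occurrence matrix (GLCM) texture statistics on masked CT
    lung parenchyma, quantifies stain area fractions and positive-cell
    densities in brightfield histology via optical-density colour
    deconvolution, summarises radiotherapy plan dose/volume metrics against
    planning goals, and links measurements with paired-lung differencing,
    balanced repeated-measures ANOVA, one-way ANOVA, Pearson correlation
    and qPCR standard-curve relative quantification. A synthetic phantom
    generator produces CT slices and stained fields with known ground
    truth so every pipeline stage is testable without raw images.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
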