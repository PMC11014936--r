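Package: actinscreen
Title: Phenotypic High-Content Screening Analytics for Hepatic Stellate Cell Deactivation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing image-based phenotypic screens that search for
    compounds deactivating activated hepatic stellate cells. Implements well-level
    quantification of filamentous-actin staining (the "Actin score": total
    fluorescence intensity over stained area), plate quality control (control-well
    coefficient of variation and Z'-factor), plate-wise mean minus k standard
    deviation hit calling, a staged primary/secondary/tertiary screening funnel,
    delta-delta-Ct relative quantification of marker genes with ANOVA against a
    vehicle control, and bulk expression-profiling analytics (TPM, gene Z-scores,
    Pearson-distance hierarchical clustering, PCA, volcano statistics). A seeded
    synthetic-data layer generates plate layouts, two-phenotype well images, large
    fast-mode screens with known ground truth, qPCR Ct tables and RNA-seq-like
    count matrices, so every stage can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    withr,
    EBImage,
    ape,
    readr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    tiff,
    patchwork
Config/testthat/edition: 3
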