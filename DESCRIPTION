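Package: stilquant
Title: Automated Stromal Tumor-Infiltrating Lymphocyte Quantification for H&E Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies stromal tumor-infiltrating lymphocyte (sTIL) density
    from class-labeled tissue rasters and cell detections of H&E-stained
    breast-cancer sections. Derives a macro-tumor outline by local tumor-area
    kernel density and morphology, defines tumor-associated stroma including
    the invasive margin, applies guideline-compliant TIL exclusion rules,
    reports density in cells per square millimeter with local-density
    heatmaps, and evaluates the biomarker with Kaplan-Meier curves, Cox
    proportional-hazards models, maximally selected rank statistics for
    cutpoint selection, and concordance against manual sTIL scores.
    Pluggable inference backends and deterministic synthetic-slide and
    synthetic-cohort generators make the full pipeline testable without
    trained models or restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    tiff,
    survival,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
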