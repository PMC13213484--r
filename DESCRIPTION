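Package: cellpaintr
Title: Morphological Profiling Pipeline for Cell Painting Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for cell painting high-content screens:
    aggregation of per-site image features to well and compound level,
    selection of reproducible features across biological repeats,
    Z-score fingerprints relative to DMSO vehicle controls, induction
    values, biosimilarity and cross-biosimilarity from Pearson
    correlation distance, region summaries, matching of fingerprints
    against bioactivity-cluster subprofiles, and relative gene
    expression by the 2^-ddCt method with ANOVA/Dunnett testing. A
    synthetic plate simulator with programmable phenotype signatures
    provides ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    ggplot2,
    jsonlite,
    multcomp,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
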