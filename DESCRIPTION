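Package: petex
Title: Dual-Timepoint PET Texture Feature Extraction and Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts a 99-feature radiomic signature (first-order
    statistics, grey-level co-occurrence, difference, run-length,
    size-zone and neighbourhood grey-tone difference matrices, and
    fractal descriptors) from segmented tumour volumes on 18F-FDG PET
    scans, with SUV conversion and decay correction, and compares
    paired early/late post-injection acquisitions with nonparametric
    statistics (Wilcoxon signed-rank, Spearman correlation, intraclass
    correlation). Includes a synthetic paired-phantom cohort generator
    for validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
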