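Package: stilsvar
Title: Multi-Reader Variability Analysis for Stromal TILs Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing inter-reader variability in stromal
    tumor-infiltrating lymphocyte (sTILs) annotations of breast-biopsy
    regions of interest (ROIs). Ingests and validates tabular multi-reader
    annotation records (four-category ROI label, percent tumor-associated
    stroma, sTILs density), pools them per ROI into label counts, Shannon
    label entropy, density means and sample variances, and tie-aware
    majority labels; stratifies ROIs into clinically motivated density
    bins and selects high- and low-variability cases at a configurable
    high:low ratio for expert review; compares reader cohorts through
    median (IQR) summary tables, majority-label frequency tables, and
    paired per-ROI deltas; and generates synthetic multi-reader cohorts
    with planted truth, cohort-specific label confusion and density
    noise, so the whole pipeline can be exercised and tested without
    access to a reader study.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
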