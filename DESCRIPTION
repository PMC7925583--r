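Package: hospitalome
Title: Longitudinal Hospital Microbiome Cohorts: Antibiotic Impact and
    Bloodstream-Infection Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal gut-microbiome cohorts of hospitalized
    allogeneic hematopoietic cell transplantation (allo-HCT) patients: a
    typed reader/validator/writer for the deidentified "hospitalome" CSV
    tables (16S ASV counts, qPCR total bacterial load, drug exposure
    intervals, transplant metadata, blood cultures, vitals), a synthetic
    cohort generator with known ground truth, composition utilities
    (relative and qPCR-scaled absolute abundance, taxonomic aggregation,
    intestinal-domination calls, 2-D embedding), inference of per-antibiotic
    effects on taxon growth rates by cross-validated ridge regression on
    consecutive-sample pairs, and time-dependent-covariate Cox
    proportional-hazards analysis of bloodstream-infection risk after
    intestinal domination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    patchwork,
    stats,
    utils,
    grid,
    grDevices,
    survival,
    Rtsne
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
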