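Package: midtracer
Title: Natural-Abundance Correction and Differential Statistics for 13C
    Isotope-Tracing Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for GC-MS stable-isotope-tracing metabolomics.
    Builds per-fragment natural-abundance correction matrices for
    TBDMS-derivatized (M-57) and underivatized fragments by isotope-pattern
    convolution, deconvolves raw isotopologue peak areas into mass isotopomer
    distributions (MIDs) by non-negative least squares, computes fractional
    enrichment and internal-standard / cell-number normalized abundances, and
    summarizes labeling per experimental condition. Includes two-group
    differential-metabolomics statistics (fold change, Student's t, exact
    Wilcoxon rank-sum, Benjamini-Hochberg FDR, pooled group summaries,
    enrichment classification) and a synthetic-data generator that simulates
    isotopologue area tables and abundance tables from declared labeling
    scenarios so every stage is testable without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
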