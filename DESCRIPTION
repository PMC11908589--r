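Package: slideqc
Title: Algorithm-Centric Quality Control for Cytology Slide Preparation
    Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quality control of whole-slide-image preparation pipelines
    from the point of view of the analysis algorithm. A preparation
    pipeline is represented by per-feature histograms of nuclei
    morphometric features extracted from a batch of slides; reference
    pipelines are calibrated with weighted distribution distances
    (Wasserstein, Hellinger/Bhattacharyya, Jensen-Shannon) and new
    batches are scored for compatibility and quality against them, with
    per-feature attribution of drift. Includes composable nuclei
    selection methods, chi-squared and minimum-redundancy
    maximum-relevance feature selection, a grid-search validation
    procedure with seed-stability refinement, a synthetic multi-pipeline
    cohort generator for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
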