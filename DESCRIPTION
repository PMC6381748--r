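Package: phosphoflux
Title: Time-Resolved Phosphoproteomic Signaling Analysis for Glucose-Stimulated Beta Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for time-course phosphoproteomics of
    glucose-stimulated insulin-secreting cells: per-time-point differential
    phosphosite statistics with fold-change and significance gates,
    trajectory clustering of phosphorylation kinetics via descriptive
    measures and k-medoids under the 1-norm, kinase-substrate enrichment
    analysis (KSEA) z-scores with permutation validation, hypergeometric
    gene-set over-representation, and quantification of oxygen-consumption
    responses as area under the curve over basal respiration. Includes a
    ground-truthed synthetic-data generator so every stage is testable
    without access to raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    pracma,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
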