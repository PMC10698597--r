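Package: embedaudit
Title: Subgroup Bias Audits for Frozen Image-Model Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing feature representations of medical image
    models for encoded protected characteristics and downstream performance
    disparities. Detects subgroup distribution shifts in embedding spaces via
    principal component projections, balanced patient subsampling, two-sample
    Kolmogorov-Smirnov tests and Benjamini-Yekutieli multiplicity correction;
    trains multilabel classification heads of fixed capacities on frozen
    embeddings; and measures per-subgroup true-positive rate, false-positive
    rate, Youden J and AUC at an operating point calibrated to a pooled
    false-positive rate, with patient-level bootstrap confidence intervals on
    demographically balanced resampled test sets. Includes a synthetic cohort
    and embedding generator with known ground-truth shift and disparity
    parameters for validating the audit end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rtsne,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
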