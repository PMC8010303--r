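Package: ProteoNet
Title: Weighted Correlation Network Analysis of CSF Proteome Profiles
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Signed weighted correlation network analysis for cerebrospinal
    fluid (CSF) proteomic abundance data: background-median normalization,
    group-wise missingness filtering, outlier-sample detection, module
    detection with eigenproteins, intramodular connectivity and hub calling,
    leave-one-out module stability, module-phenotype testing, differential
    correlation via Fisher's r-to-z, hypergeometric set enrichment and
    cross-network module preservation, and random-intercept mixed-model
    screening of longitudinal protein trajectories. Includes a synthetic-data
    generator with planted modules, group shifts, decorrelated pairs and
    longitudinal slopes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    nlme,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
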