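Package: ddmspDetect
Title: Cell-Free DNA Methylation Marker Selection and Droplet Digital
    MSP Detection Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building cell-free DNA (cfDNA) methylation assays
    for cancer detection. Implements candidate marker selection from
    Infinium-style beta-value matrices using balanced group means and
    four top-k selection conditions; absolute quantification of droplet
    digital methylation-specific PCR (ddMSP) reactions via supervised
    amplitude-threshold optimisation and Poisson correction; assembly of
    a 15-variable per-sample feature table (12 marker log10
    concentrations, their mean, a geometric-mean internal-control cfDNA
    concentration, and a positive-marker count); exhaustive
    variable-subset selection of a linear support vector machine
    detection index by leave-one-out cross-validation; the fixed
    published six-variable detection-index model; and evaluation
    statistics (ROC/AUC, confusion metrics, stage-ordered
    Jonckheere-Terpstra trend tests, subtype and age-bias analyses,
    stratified train/validation splitting). A synthetic-data module
    generates array, cohort and droplet-level datasets with the
    statistical structure such a study assumes, so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    e1071,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
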