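Package: phenoscreen
Title: Graphical Data-Processing Workflow for High-Throughput Screening of
    Radiation-Induced Plant Mutants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a reusable pipeline for screening radiation-induced
    mutants from high-throughput plant-phenotyping output: standardization and
    principal-component factor scores from multi-trait phenotype tables,
    Ward/Euclidean hierarchical clustering, pairwise confidence-ellipse outlier
    calling in factor-score space, logistic growth-curve fitting and
    growth-parameter screening, combination of static and dynamic calls, and
    classifier-style evaluation (accuracy, false positive rate, false negative
    rate) against known mutant labels.  A synthetic-population generator and a
    small plate-image emulator provide end-to-end test data in place of
    proprietary imaging-system output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    minpack.lm,
    jsonlite,
    yaml,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
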