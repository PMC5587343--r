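Package: methdrift
Title: Detection of Passage-Dependent DNA Methylation Drift in Cultured
    Pluripotent Stem Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A screen for recurrent culture-induced epigenetic aberrations in
    human pluripotent stem cells. Integrates probe-level DNA methylation
    (beta values) with matched gene expression across low- and high-passage
    sample groups to detect genes that become hypermethylated and silenced
    during prolonged culture. Provides expression-based virtual karyotyping
    for sample QC, per-probe methylation-versus-passage regression with
    genome-wide slope ranking, variability ranking, hierarchical clustering
    with branch-composition tests, hypergeometric cross-dataset overlap
    statistics, knockdown differential-expression filtering, McrBC-qPCR
    methylation quantification, and a synthetic-data generator that plants
    known drift genes so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
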