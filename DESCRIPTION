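Package: raexi
Title: Analysis of Random Allelic Expression Imbalance in Clonal Cell
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify and model random allelic expression imbalance
    (RAExI) across clonal cell lines from an F1 hybrid cross. Computes and
    classifies allelic expression and accessibility ratios from allele-specific
    read counts, decomposes per-gene clonal ratio distributions into Gaussian
    mixture components with BIC model selection, bootstrap likelihood-ratio
    tests and bootstrap confidence intervals, tests stable monoallelic
    expression against transcriptional bursting in nascent RNA-FISH cell
    tallies with a binomial goodness-of-fit model, scans accessible-chromatin
    peaks around a gene's TSS for allelic accessibility that predicts allelic
    expression, and provides the downstream dosage, stability, epidrug-screen
    and dose-response statistics. Includes seed-deterministic synthetic-data
    generators with ground-truth labels for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
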