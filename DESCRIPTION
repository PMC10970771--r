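Package: pdmir
Title: Plasma miRNA Biomarker Discovery and Validation for Parkinson's
    Disease Dementia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-phase analysis pipeline for circulating plasma miRNA
    biomarkers of cognitive decline in Parkinson's disease. The discovery
    phase screens a supersaturated small-RNA-seq count matrix (TMM
    normalization, low-expression trimming, batch location adjustment) with
    a Dantzig-type L1 selector whose tuning parameter is chosen by
    cross-validated logistic-regression AUC, ranking candidates by their
    shrink-to-zero order along the solution path. The validation phase
    converts droplet digital PCR well counts to concentrations by Poisson
    occupancy statistics, forms a target/reference miRNA ratio under QC and
    IQR outlier rules, compares groups nonparametrically (Kruskal-Wallis
    with Dunn's post hoc tests), correlates the ratio with cognitive domain
    scores, and evaluates AIC-reduced logistic models by bootstrap ROC
    analysis. A synthetic-data module generates negative-binomial count
    matrices and droplet-level ddPCR cohorts so every stage is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    edgeR,
    stats,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
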