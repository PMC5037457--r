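Package: dynaSILAC
Title: Dynamic SILAC Protein Turnover and Label-Free Abundance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint analysis of forward dynamic SILAC (stable-isotope labeling
    by amino acids in cell culture) proteomics experiments. From a single
    peptide-level intensity table the package quantifies label-free protein
    abundance (total peptide intensity, robust-median scaling, peptide-to-
    protein rollup, log2 transform, z-scoring, QC-pool coefficient of
    variation) and per-peptide protein turnover via the relative isotope
    abundance (RIA), including precursor-pool RIA estimation from a doubly
    lysine-labeled reporter peptide and first-order turnover-rate recovery.
    Downstream stages cover error-weighted ANOVA, per-time t-tests with
    Bonferroni and Benjamini-Hochberg correction, a four-criterion
    differential-expression filter, three-way temporal-trend classification,
    PCA quality control with confidence ellipses, and permutation-based gene
    set enrichment on abundance and turnover rankings. A synthetic-data
    generator with known ground truth (turnover rates, fold changes, pool
    RIA) emulates a time-course design under normal and simulated
    microgravity so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
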