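Package: mirProgression
Title: Multilevel miRNA-mRNA-Pathway Integromics Across Ordered Tumor
    Progression Stages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for multilevel integrative analysis of expression
    profiles measured across an ordered series of tumor-progression
    stages (normal-like, preneoplastic, in situ, invasive), as in the
    MCF10A-based breast cancer progression panel. Provides zero-variance
    and SD-quantile feature filtering, quantile normalization, per-feature
    one-way ANOVA with Benjamini-Hochberg FDR control, Tukey HSD post-hoc
    contrasts, attribution of expression changes to adjacent stage
    transitions, K-means mapping of features onto eight predefined
    progression-pattern templates with silhouette-based quality filtering,
    parametric analysis of gene set enrichment (PAGE) Z-scores,
    integration of miRNA pattern groups with reversed-pattern predicted
    target genes via TargetScan-style context scores, derivation of
    target pathways by gene-set membership overlap, Pearson-correlation
    network construction, and median-split survival analysis
    (Kaplan-Meier, log-rank, multivariate Cox with Efron ties). A
    synthetic-data generator with known planted truth emulates the full
    study design so every pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    survival,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
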