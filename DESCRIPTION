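Package: crossOmics
Title: Joint Compositional Factorization of Paired Microbiome and
    Metabolome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for linking gut microbiome composition to the fecal
    metabolome in designed cohort studies. Implements the robust centered
    log-ratio (rclr) transformation for sparse compositional tables,
    OptSpace-style low-rank matrix completion, single-table robust
    Aitchison PCA (RPCA) ordination, joint multi-table factorization with
    shared sample scores and cross-validated reconstruction, cross-omic
    feature correlations, feature-set natural log-ratio biomarkers,
    PERMANOVA and rank-based group tests, and two-group PLS-DA with VIP
    feature selection. A synthetic paired-cohort generator with planted
    low-rank structure and opposing family enrichments makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    vegan,
    biomformat,
    lme4,
    lmerTest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
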