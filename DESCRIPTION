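Package: mirpath
Title: Integration of Paired miRNA and mRNA Expression Profiles to
    Identify miRNA-Regulated Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an integration analysis for matched miRNA and mRNA
    expression cohorts: random-variance-model (RVM) moderated t-tests for
    differential expression in small samples, Pearson anti-correlation
    screening of miRNA-mRNA pairs, intersection with target-prediction
    tables, Fisher's exact / chi-squared gene-set enrichment with
    Benjamini-Hochberg FDR, and bipartite miRNA-gene network degree
    analysis with regulator and hub calling. A synthetic-cohort generator
    plants known repressive miRNA-target relationships so every stage of
    the pipeline can be benchmarked against ground truth. Validation-layer
    statistics (2^-ddCt relative quantification, Pearson/Spearman
    correlation, two-sample t and one-way ANOVA, assay ratio utilities)
    are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
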