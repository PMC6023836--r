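Package: mirtempo
Title: Integrative Temporal Analysis of Paired miRNA and mRNA Expression
Version: 0.1.0
Authors@R: person("Mirtempo", "Developers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the integrative analysis of paired microRNA and
    poly(A)-RNA expression time courses, as arise in developmental
    transcriptomics of the heart. Provides empirical-Bayes moderated
    differential expression against configurable reference stages, fuzzy
    c-means clustering of standardized stage profiles with advisory cluster
    number selection, collation and percentile scoring of miRNA-target
    interaction resources, Kendall anti-correlation networks between miRNA
    and gene clusters, miRNA prioritization by counts of anti-correlated
    differentially expressed targets, hypergeometric category enrichment,
    and a deterministic synthetic-data generator with planted repressive
    miRNA-target interactions for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
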