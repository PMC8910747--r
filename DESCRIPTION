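Package: netsubtype
Title: Transcriptomic Disease Subtyping with Co-Expression Network Analysis
Version: 0.1.0
Authors@R:
    person("netsubtype", "developers", email = "netsubtype@example.org",
           role = c("aut", "cre"))
Description: A fully data-driven workflow for discovering disease subtypes from
    bulk RNA-seq counts and characterizing them at the network level. Provides
    a negative-binomial cohort simulator with planted subtypes, batch effects
    and condition-specific correlation structure; count preprocessing
    (gene-wise integration, Grubbs outlier screening, low-count filtering,
    negative-binomial quantile-mapping batch adjustment, log2-CPM); cluster
    tendency assessment (Hopkins), best-k estimation and a multi-algorithm
    clustering portfolio selected by internal validity (silhouette, Dunn);
    moderated-t differential expression with empirical-Bayes variance
    shrinkage and BH-FDR; PCIT partial-correlation co-expression networks with
    label-propagation communities and centrality scoring; permutation-based
    network comparison tests (global strength, structure, per-edge invariance);
    regulatory impact factor (RIF) scoring of transcription factors;
    over-representation and gene-disease association analysis against local
    gene-set collections; and a sequential drug-gene interaction filter for
    repurposing candidates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
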