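Package: rgsig
Title: Robust Differential-Expression Gene Signatures via Subsampling Stability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives robust case/control gene-expression signatures by
    measuring the stability of top-k differential-expression lists under
    repeated stratified subsampling of a combined cohort, quantified by the
    pairwise list-overlap statistic. Includes directional t-testing with
    Benjamini-Hochberg correction and a top-fraction/FDR selection rule,
    hierarchical clustering of samples on the signature with Newick export,
    hub-gene ranking in protein-protein interaction networks by degree and
    betweenness, hypergeometric over-representation analysis with
    permutation-based FDR, and Kaplan-Meier / log-rank / proportional-hazards
    survival analysis with a coefficient-weighted risk score. A synthetic-data
    module generates expression, survival, network and gene-set fixtures with
    planted structure so every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    stats,
    survival,
    utils,
    withr
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
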