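Package: comorbidnet
Title: Comorbidity Gene-Set, Pathway Cross-Talk, and Interactome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the shared genetic architecture of two
    comorbid diseases from curated susceptibility gene lists. Implements
    gene-list reading, score-based filtering, merging and intersection;
    hypergeometric over-representation analysis with Benjamini-Hochberg
    false-discovery-rate control and shared/disease-specific pathway
    classification; pathway cross-talk scoring with Jaccard and Overlap
    coefficients and construction of pathway-pathway-gene networks; and
    protein-protein interactome cleaning, disease-subnetwork extraction,
    network overlap, and guilt-by-association prioritization of novel
    candidate genes by their number of shared-gene neighbors. A synthetic
    data generator with planted candidates and planted enriched pathways
    makes every stage testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
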