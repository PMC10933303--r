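Package: paddydiv
Title: Coalescent Model Selection, Niche Overlap, and Morphospace Analysis
    for Rice Paddy Snakes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A three-pronged toolkit for studying the diversification of
    Southeast Asian rice paddy snakes (Hypsiscopus) and similarly structured
    three-population systems. Provides (i) a Wright-Fisher coalescent
    simulator with infinite-sites mutation under six demographic scenarios
    on the fixed topology (murphyi,(plumbeus,matannensis)) -- isolation with
    and without migration, population-size change, and founder-event
    bottlenecks -- together with msABC-style multilocus summary statistics
    and rejection approximate Bayesian computation for model selection,
    cross-validated model classification, and posterior divergence dating;
    (ii) gridded environmental-space quantification of niche overlap
    (Schoener's D), permutation niche equivalency and background similarity
    tests, COUE niche-dynamics indices, correlation-based climate-layer
    pruning, and climate envelopes; (iii) morphospace analysis of mixed-type
    trait tables via PCA and linear discriminant analysis with exact
    binomial accuracy intervals. A synthetic-data module generates phased
    multilocus alignments, environmental rasters with occurrence records,
    and group-structured trait tables so the whole pipeline runs without
    external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    MASS,
    Biostrings,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
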