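Package: gges
Title: Grouped Greedy Equivalence Search for Constrained Causal Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Score-based causal structure learning for clinical cohort data in
    which variables are partitioned into a causal group and an outcome group,
    and outcome variables are constrained to be sinks. Implements a greedy
    forward/backward search over directed acyclic graphs maximizing a
    decomposable Gaussian BIC score under the group constraint, intervention
    do-calculus adjustment (IDA) effect estimation and ranking, exact total
    causal effects on weighted ground-truth graphs, structural accuracy
    metrics (adjacency and arrowhead precision/recall) with k-fold
    cross-validation stability, and a synthetic clinical-cohort generator
    with a known ground-truth structural equation model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
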