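Package: assemblyNet
Title: Weighted Gene Co-Expression Bionetwork Analysis for
    Multi-Treatment Expression Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for gene-bionetwork analysis of
    multi-treatment microarray experiments, modelled on studies of
    ovarian primordial follicle assembly in which neonatal ovaries are
    perturbed with a panel of growth factors and hormones. Implements
    array-level quality control, per-treatment differential-expression
    signature lists under a three-criterion filter (fold change, t test,
    absolute difference), weighted co-expression network construction
    with scale-free soft-threshold selection, topological overlap module
    detection by average-linkage clustering, intramodular-connectivity
    hub selection, gene-set over-representation and overlap statistics,
    and ranking of interaction subnetworks from user-supplied edge
    lists. Includes a synthetic-data generator with planted modules,
    treatment effects, batch effects and an outlier array for
    parameter-recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml,
    withr,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
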