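Package: consensusMerge
Title: Merged Consensus Clustering for Cluster Stability Assessment
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Resampling-based consensus clustering for gene expression and
    other feature-by-condition matrices. Repeatedly subsamples the rows of a
    data matrix, clusters each subsample with any registered clustering
    backend, and accumulates connectivity and indicator matrices into a
    consensus matrix recording how often each pair of features co-clusters
    when both are sampled. Consensus matrices from different algorithms run
    at the same cluster number can be combined by weighted averaging into a
    merged consensus matrix that compensates for algorithm-specific
    sensitivities such as the outlier handling of hierarchical methods.
    Cluster robustness and per-member membership robustness are scored
    against a full-data reference clustering, and the number of clusters is
    estimated from peaks in the change of the area under the empirical CDF
    of consensus values. Includes a synthetic expression-profile generator
    for validating the whole pipeline, delimited-text input/output with
    provenance sidecars, and diagnostic plots.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    cluster,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Clustering, GeneExpression, Software
RoxygenNote: 7.3.3
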