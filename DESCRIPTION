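Package: MorphoPart
Title: Morphometric Species Delimitation by Nest-Centroid Clustering and
    Recursive Gap-Statistic Partitioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Objective species delimitation from continuous morphometric
    trait tables with nested sampling structure (workers within nests within
    species), as used in integrative ant taxonomy. Implements nest-centroid
    clustering (linear discriminant analysis with nest samples as groups,
    followed by hierarchical clustering of nest centroids in discriminant
    space), cluster-number estimation and assignment by recursive application
    of the Gap statistic with hierarchical and k-means engines (PART),
    confirmation of cluster hypotheses by leave-one-out cross-validated LDA
    with wildcard handling for incongruently partitioned samples,
    multivariate ratio analysis (isometric size, shape projection, and an
    LDA ratio extractor for diagnostic trait ratios), a ratio-threshold
    dichotomous identification key engine, per-species summary statistics,
    and a synthetic-data generator emulating nest-structured morphometrics
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    ape,
    S4Vectors,
    SummarizedExperiment
Suggests:
    cluster,
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'confirm.R'
    'gap-part.R'
    'key.R'
    'methods.R'
    'morpho-io.R'
    'mra.R'
    'nc-clustering.R'
    'pipeline.R'
    'sikorai-reference.R'
    'simulate.R'
    'summary-report.R'
    'utils.R'
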