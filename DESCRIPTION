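Package: flowImpute
Title: Imputation and Analysis of Massively Multiplexed Flow Cytometry Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end workflow for Infinity Flow style experiments, in which
    hundreds of exploratory surface markers are measured one capture at a time
    on top of a shared backbone antibody panel and then imputed onto a common
    set of events. Provides a native FCS 3.0/3.1 reader and writer, logicle
    and arcsinh transformations, gradient-boosted regression of each
    exploratory marker on the backbone channels with held-out validation,
    optional isotype background correction by a linear model, pooling or
    reference-file assembly of the final annotated event-by-feature matrix,
    seeded PCA/UMAP/Leiden wrappers, cluster marker discovery by correlation
    to idealized cluster profiles, nearest-centroid label transfer from
    reference atlases, and a fully synthetic panel generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    xgboost,
    igraph,
    RANN,
    uwot,
    rhdf5,
    arrow,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
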