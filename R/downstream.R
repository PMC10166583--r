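#' PCA, neighbor graph, Leiden clustering and UMAP
#'
#' The standard single-cell embedding stack on the annotated event-by-feature
#' matrix: features are standardized (for embedding only), projected onto the
#' top principal components, a k-nearest-neighbor graph is built, Leiden
#' community detection is run on it, and (optionally) a 2-D UMAP is
#' computed. Every stochastic stage is seeded, so fixed seeds give identical
#' labels and coordinates across runs.
#'
#' @param x an [ImputedExperiment-class] or an events x features numeric
#'   matrix.
#' @param nPcs number of principal components (default 30; clamped with a
#'   warning when it reaches the feature or event count).
#' @param nNeighbors k for the kNN graph and UMAP (default 15).
#' @param resolution Leiden resolution (default 1.0, modularity objective).
#' @param seed integer seed.
#' @param computeUmap compute the 2-D UMAP embedding (default `TRUE`).
#' @return For a matrix: a [ClusterResult-class] (labels `"0"`, `"1"`, ...
#'   ordered by decreasing cluster size). For an
#'   [ImputedExperiment-class]: the experiment with `colData()$cluster`,
#'   `reducedDims` `PCA` (+ `UMAP`) filled in and the
#'   [ClusterResult-class] in `metadata()$clustering`.
#' @export
embedAndCluster <- function(x, nPcs = 30, nNeighbors = 15, resolution = 1.0,
                            seed = 1, computeUmap = TRUE) {
    if (is(x, "ImputedExperiment")) {
        M <- t(SummarizedExperiment::assay(x, "exprs"))
        cr <- embedAndCluster(M, nPcs, nNeighbors, resolution, seed,
                              computeUmap)
        SummarizedExperiment::colData(x)$cluster <- cr@labels
        SingleCellExperiment::reducedDim(x, "PCA") <-
            attr(cr, "pca")[, , drop = FALSE]
        if (nrow(cr@embedding))
            SingleCellExperiment::reducedDim(x, "UMAP") <- cr@embedding
        S4Vectors::metadata(x)$clustering <- cr
        return(x)
    }
    stopifnot(is.matrix(x))
    n <- nrow(x)
    if (n < nNeighbors + 1)
        .stopf("need at least nNeighbors + 1 = %d events (got %d)",
               nNeighbors + 1, n)

    sds <- apply(x, 2, stats::sd)
    keep <- which(sds > 0)
    xs <- scale(x[, keep, drop = FALSE])
    if (nPcs >= length(keep)) {
        .warnf("nPcs = %d clamped to %d (number of usable features)",
               nPcs, length(keep))
        nPcs <- length(keep)
    }
    nPcs <- min(nPcs, n - 1L)
    pca <- stats::prcomp(xs, rank. = nPcs, center = FALSE,
                         scale. = FALSE)$x

    nn <- RANN::nn2(pca, k = min(nNeighbors + 1, n))$nn.idx
    edges <- cbind(rep(seq_len(n), ncol(nn) - 1),
                   as.vector(nn[, -1, drop = FALSE]))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::simplify(g)

    rs <- .Random.seed.save()
    on.exit(.Random.seed.restore(rs))
    set.seed(as.integer(seed))
    comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                   resolution = resolution,
                                   n_iterations = 5)
    mem <- igraph::membership(comm)
    # contiguous ids from 0, ordered by decreasing cluster size
    sizes <- sort(table(mem), decreasing = TRUE)
    relab <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
    labels <- as.character(relab[as.character(mem)])

    emb <- matrix(numeric(0), 0, 2)
    if (computeUmap) {
        set.seed(as.integer(seed))
        emb <- uwot::umap(pca, n_neighbors = min(nNeighbors, n - 1),
                          n_threads = 1, n_sgd_threads = 1)
        colnames(emb) <- c("UMAP1", "UMAP2")
    }
    cr <- new("ClusterResult", labels = labels, resolution = resolution,
              nNeighbors = as.integer(nNeighbors), seed = as.integer(seed),
              embedding = emb)
    attr(cr, "pca") <- pca
    cr
}

#' Sub-cluster one cluster
#'
#' Reruns [embedAndCluster()] on the events of a single parent cluster.
#' Child labels are namespaced `"parent.child"`; all other events keep their
#' labels untouched.
#'
#' @param x an [ImputedExperiment-class] (with `colData()$cluster`) or an
#'   events x features matrix.
#' @param labels existing cluster labels (taken from `colData()` for an
#'   experiment).
#' @param parentLabel cluster id to subdivide.
#' @param nPcs,nNeighbors,resolution,seed,computeUmap see
#'   [embedAndCluster()].
#' @return A [ClusterResult-class] whose `labels` cover all events (outside
#'   events unchanged); for an experiment input, the updated experiment.
#' @export
subcluster <- function(x, parentLabel, labels = NULL, nPcs = 30,
                       nNeighbors = 15, resolution = 1.0, seed = 1,
                       computeUmap = FALSE) {
    if (is(x, "ImputedExperiment")) {
        labels <- SummarizedExperiment::colData(x)$cluster
        if (is.null(labels))
            .stopf("experiment has no cluster labels; run embedAndCluster first")
        M <- t(SummarizedExperiment::assay(x, "exprs"))
        cr <- subcluster(M, parentLabel, labels, nPcs, nNeighbors,
                         resolution, seed, computeUmap)
        SummarizedExperiment::colData(x)$cluster <- cr@labels
        return(x)
    }
    stopifnot(is.matrix(x), length(labels) == nrow(x))
    parentLabel <- as.character(parentLabel)
    idx <- which(labels == parentLabel)
    if (length(idx) == 0) .stopf("cluster '%s' is empty", parentLabel)
    if (length(idx) < nNeighbors + 1)
        .stopf("cluster '%s' has %d events; need at least nNeighbors + 1 = %d",
               parentLabel, length(idx), nNeighbors + 1)
    sub <- embedAndCluster(x[idx, , drop = FALSE], nPcs, nNeighbors,
                           resolution, seed, computeUmap)
    out <- as.character(labels)
    out[idx] <- paste0(parentLabel, ".", sub@labels)
    new("ClusterResult", labels = out, resolution = resolution,
        nNeighbors = as.integer(nNeighbors), seed = as.integer(seed),
        embedding = sub@embedding)
}
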