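#' MarkerFinder: correlation of features to idealized cluster profiles
#'
#' For each feature f and cluster c, computes the Pearson correlation of f's
#' values with the idealized indicator profile of c (1 for events in c, 0
#' otherwise). Each feature is assigned to the cluster maximizing this
#' correlation (ties broken by lowest cluster id); within each cluster,
#' assigned features are ranked by descending correlation and the top `topN`
#' are returned. This is the single-pass indicator-correlation form of the
#' algorithm.
#'
#' Zero-variance features are excluded with a warning; clusters with fewer
#' than 2 events are excluded from assignment with a warning.
#'
#' @param X events x features numeric matrix with column names.
#' @param labels cluster label per event (>= 2 usable clusters).
#' @param topN markers reported per cluster (default 3).
#' @return data.frame with `feature`, `cluster`, `r`, `rank` (at most `topN`
#'   rows per cluster, ranked by `r`).
#' @export
markerFinder <- function(X, labels, topN = 3) {
    stopifnot(is.matrix(X), length(labels) == nrow(X),
              !is.null(colnames(X)))
    labels <- as.character(labels)
    empty <- data.frame(feature = character(), cluster = character(),
                        r = numeric(), rank = integer())

    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0)) {
        .warnf("excluding zero-variance feature(s): %s",
               paste(colnames(X)[sds == 0], collapse = ", "))
        X <- X[, sds > 0, drop = FALSE]
    }
    if (ncol(X) == 0) {
        .warnf("all features are constant; no markers to report")
        return(empty)
    }
    counts <- table(labels)
    small <- names(counts)[counts < 2]
    if (length(small))
        .warnf("excluding cluster(s) with < 2 events: %s",
               paste(small, collapse = ", "))
    clusters <- sort(setdiff(names(counts), small))
    if (length(clusters) < 2)
        .stopf("markerFinder needs at least 2 clusters with >= 2 events")

    ind <- vapply(clusters, function(cl) as.numeric(labels == cl),
                  numeric(length(labels)))
    r <- stats::cor(X, ind)           # features x clusters

    best <- apply(r, 1, function(v) which(v == max(v))[1])  # lowest id ties
    out <- lapply(seq_along(clusters), function(ci) {
        feats <- which(best == ci)
        if (!length(feats)) return(NULL)
        ord <- feats[order(r[feats, ci], decreasing = TRUE)]
        ord <- utils::head(ord, topN)
        data.frame(feature = colnames(X)[ord], cluster = clusters[ci],
                   r = r[ord, ci], rank = seq_along(ord))
    })
    out <- do.call(rbind, c(out, make.row.names = FALSE))
    if (is.null(out)) empty else out
}

#' Read reference centroid profiles
#'
#' Reads a CSV/TSV of reference population centroids: one row per label
#' (first column), one column per feature.
#'
#' @param path file path (delimiter inferred from the extension).
#' @return labels x features numeric matrix.
#' @export
readReferenceProfiles <- function(path) {
    sep <- if (grepl("\\.tsv$", path)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    storage.mode(m) <- "double"
    m
}

#' Nearest-centroid label transfer
#'
#' Assigns each query event the reference label whose centroid it correlates
#' with best over the shared features (Pearson). This is a deliberate
#' simplification of community-alignment label transfer to its
#' nearest-centroid core: no community matching or iterative refinement is
#' performed.
#'
#' @param query events x features matrix (or [ImputedExperiment-class]).
#' @param reference labels x features centroid matrix (see
#'   [readReferenceProfiles()]).
#' @param featureMap optional named character vector renaming query features
#'   to reference feature names (`names` = query, values = reference), e.g.
#'   protein names to the genes encoding them.
#' @param minScore correlation floor below which events are labeled
#'   `"unassigned"` (default 0.1).
#' @return data.frame with `label` and `score` per query event. Exact ties
#'   are broken towards the lexicographically smallest label, with a
#'   warning.
#' @export
labelTransfer <- function(query, reference, featureMap = NULL,
                          minScore = 0.1) {
    if (is(query, "ImputedExperiment"))
        query <- t(SummarizedExperiment::assay(query, "exprs"))
    stopifnot(is.matrix(query), is.matrix(reference),
              !is.null(colnames(query)), !is.null(colnames(reference)))
    qn <- colnames(query)
    if (!is.null(featureMap)) {
        hit <- qn %in% names(featureMap)
        qn[hit] <- unname(featureMap[qn[hit]])
    }
    shared <- intersect(qn, colnames(reference))
    if (length(shared) < 3)
        .stopf("need >= 3 shared features; query has [%s], reference has [%s]",
               paste(qn, collapse = ", "),
               paste(colnames(reference), collapse = ", "))
    Q <- query[, match(shared, qn), drop = FALSE]
    C <- reference[, shared, drop = FALSE]

    rowStd <- function(m) {
        mu <- rowMeans(m)
        s <- sqrt(rowSums((m - mu)^2))
        (m - mu) / ifelse(s == 0, 1, s)
    }
    scores <- rowStd(Q) %*% t(rowStd(C))   # events x labels, Pearson r

    ord <- order(rownames(C))              # lexicographic tie-break
    scoresO <- scores[, ord, drop = FALSE]
    labsO <- rownames(C)[ord]
    # scores within 1e-12 of the row maximum count as tied (exact equality
    # is not robust to BLAS accumulation order)
    tol <- 1e-12
    best <- scoresO[cbind(seq_len(nrow(scoresO)),
                          max.col(scoresO, ties.method = "first"))]
    nearMax <- scoresO >= best - tol
    lab <- labsO[max.col(nearMax, ties.method = "first")]
    if (any(rowSums(nearMax) > 1))
        .warnf("tie(s) in centroid correlation broken towards the lexicographically smallest label")
    lab[best < minScore] <- "unassigned"
    data.frame(label = lab, score = best)
}
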