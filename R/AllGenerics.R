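#' @name accessors
#' @title Accessors for flowImpute classes
#' @param object,x an object.
#' @param value replacement value.
#' @description Accessor generics for [EventMatrix-class] and friends: the
#'   intensity matrix (`exprs`), channel descriptor table (`channels`),
#'   verbatim FCS keywords (`keywords`), provenance path (`sourcePath`),
#'   and dimensions (`nEvents`, `nChannels`, `channelNames`).
NULL

#' @rdname accessors
#' @export
setGeneric("exprs", function(object) standardGeneric("exprs"))
#' @rdname accessors
#' @export
setGeneric("exprs<-", function(object, value) standardGeneric("exprs<-"))
#' @rdname accessors
#' @export
setGeneric("channels", function(object) standardGeneric("channels"))
#' @rdname accessors
#' @export
setGeneric("keywords", function(object) standardGeneric("keywords"))
#' @rdname accessors
#' @export
setGeneric("sourcePath", function(object) standardGeneric("sourcePath"))
#' @rdname accessors
#' @export
setGeneric("nEvents", function(object) standardGeneric("nEvents"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("channelRoles", function(object) standardGeneric("channelRoles"))
#' @rdname accessors
#' @export
setGeneric("channelRoles<-", function(object, value) standardGeneric("channelRoles<-"))

#' @rdname accessors
#' @export
setMethod("exprs", "EventMatrix", function(object) object@exprs)

#' @rdname accessors
#' @export
setMethod("exprs<-", "EventMatrix", function(object, value) {
    stopifnot(is.matrix(value), ncol(value) == nrow(object@channels))
    colnames(value) <- object@channels$short_name
    object@exprs <- value
    validObject(object)
    object
})

#' @rdname accessors
#' @export
setMethod("channels", "EventMatrix", function(object) object@channels)

#' @rdname accessors
#' @export
setMethod("keywords", "EventMatrix", function(object) object@keywords)

#' @rdname accessors
#' @export
setMethod("sourcePath", "EventMatrix", function(object) object@sourcePath)

#' @rdname accessors
#' @export
setMethod("nEvents", "EventMatrix", function(object) nrow(object@exprs))

#' @rdname accessors
#' @export
setMethod("nChannels", "EventMatrix", function(object) ncol(object@exprs))

#' @rdname accessors
#' @export
setMethod("channelNames", "EventMatrix", function(object) object@channels$short_name)

#' @rdname accessors
#' @export
setMethod("channelRoles", "EventMatrix", function(object) {
    stats::setNames(object@channels$role, object@channels$short_name)
})

#' @rdname accessors
#' @export
setMethod("channelRoles<-", "EventMatrix", function(object, value) {
    stopifnot(length(value) == nrow(object@channels))
    object@channels$role <- as.character(value)
    object
})

setMethod("show", "EventMatrix", function(object) {
    cat("EventMatrix:", nrow(object@exprs), "events x",
        ncol(object@exprs), "channels\n")
    tab <- table(object@channels$role)
    cat("  roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    if (nzchar(object@sourcePath))
        cat("  source:", object@sourcePath, "\n")
})

setMethod("show", "LogicleParams", function(object) {
    cat(sprintf("LogicleParams(T=%g, W=%g, M=%g, A=%g)\n",
                object@T, object@W, object@M, object@A))
})

setMethod("show", "MarkerModel", function(object) {
    cat(sprintf("MarkerModel '%s' <- %d backbone channels [%s]\n",
                object@markerName, length(object@backboneNames),
                object@sourceFile))
    cat(sprintf("  validation: MSE=%.4g MAE=%.4g r=%.4f (n=%d)\n",
                object@valMSE, object@valMAE, object@valR,
                length(object@split@valIdx)))
})

setMethod("show", "ClusterResult", function(object) {
    cat("ClusterResult:", length(object@labels), "events,",
        length(unique(object@labels)), "clusters",
        sprintf("(resolution=%g, k=%d)\n", object@resolution,
                object@nNeighbors))
})

setMethod("show", "SyntheticPanelSpec", function(object) {
    cat(sprintf(
        "SyntheticPanelSpec: %d populations, %d backbone (+%d derived), %d markers, %d isotype groups, %d events/file, scale=%s\n",
        length(object@populationWeights), ncol(object@backboneMeans),
        length(object@derivedBackbone), length(object@markers),
        length(object@isotypes), object@nEventsPerFile, object@scale))
})

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterResult", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("validationMetrics", function(object) standardGeneric("validationMetrics"))

#' @rdname accessors
#' @export
setMethod("validationMetrics", "MarkerModel", function(object) {
    c(mse = object@valMSE, mae = object@valMAE, r = object@valR)
})
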