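#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' EventMatrix: one FCS file in memory
#'
#' Holds the event-by-channel intensity matrix of a single flow cytometry
#' capture together with its channel descriptors and the verbatim TEXT-segment
#' keywords of the source file.
#'
#' The `channels` slot is a [S4Vectors::DataFrame] with one row per channel
#' and columns `short_name` (`$PnN`), `stain_name` (`$PnS`, `NA` when absent),
#' `range` (`$PnR`), `ampl_f1`/`ampl_f2` (`$PnE` decades and offset; `(0,0)`
#' means linear) and `role`, one of `"backbone"`, `"infinity"`, `"isotype"`,
#' `"passthrough"`, `"scatter"` or `"time"`.
#'
#' @slot exprs numeric matrix, events in rows, channels in columns.
#' @slot channels `DataFrame` of channel descriptors, one row per column of
#'   `exprs`.
#' @slot keywords named character vector of all TEXT-segment keywords.
#' @slot sourcePath path the object was read from (`""` for in-memory data).
#'
#' @seealso [readFCS()], [writeFCS()], [eventMatrix()]
#' @export
setClass("EventMatrix",
    representation(
        exprs = "matrix",
        channels = "DataFrame",
        keywords = "character",
        sourcePath = "character"
    )
)

setValidity("EventMatrix", function(object) {
    msg <- character()
    ch <- object@channels
    need <- c("short_name", "stain_name", "range", "ampl_f1", "ampl_f2", "role")
    if (!all(need %in% colnames(ch)))
        msg <- c(msg, paste0("channels must have columns: ",
                             paste(need, collapse = ", ")))
    if (ncol(object@exprs) != nrow(ch))
        msg <- c(msg, "ncol(exprs) must equal nrow(channels)")
    if ("short_name" %in% colnames(ch)) {
        sn <- ch$short_name
        if (any(!nzchar(sn)) || anyNA(sn))
            msg <- c(msg, "channel short_name must be non-empty")
        if (anyDuplicated(sn))
            msg <- c(msg, "channel short_name must be unique within a file")
    }
    if (nrow(object@exprs) > 0 && any(!is.finite(object@exprs)))
        msg <- c(msg, "all event values must be finite")
    if (length(msg)) msg else TRUE
})

#' Construct an EventMatrix
#'
#' @param exprs numeric matrix, events x channels.
#' @param channelNames character vector of channel short names (`$PnN`);
#'   defaults to `colnames(exprs)`.
#' @param stainNames optional character vector of stain names (`$PnS`).
#' @param roles channel roles; defaults to [guessRoles()] of the names.
#' @param range per-channel `$PnR` range; default `262144`.
#' @param keywords named character vector of extra keywords to carry.
#' @param sourcePath provenance path.
#' @return An [EventMatrix-class] object.
#' @examples
#' m <- matrix(rexp(60, 1 / 1000), 20, 3,
#'             dimnames = list(NULL, c("FSC-A", "CD3", "PE")))
#' em <- eventMatrix(m)
#' nEvents(em)
#' @export
eventMatrix <- function(exprs, channelNames = colnames(exprs),
                        stainNames = NULL, roles = NULL,
                        range = 262144, keywords = character(),
                        sourcePath = "") {
    exprs <- as.matrix(exprs)
    storage.mode(exprs) <- "double"
    if (is.null(channelNames))
        channelNames <- paste0("P", seq_len(ncol(exprs)))
    if (is.null(roles)) roles <- guessRoles(channelNames)
    if (is.null(stainNames)) stainNames <- rep(NA_character_, ncol(exprs))
    ch <- DataFrame(
        short_name = as.character(channelNames),
        stain_name = as.character(stainNames),
        range = rep_len(as.numeric(range), ncol(exprs)),
        ampl_f1 = rep(0, ncol(exprs)),
        ampl_f2 = rep(0, ncol(exprs)),
        role = rep_len(as.character(roles), ncol(exprs))
    )
    colnames(exprs) <- ch$short_name
    new("EventMatrix", exprs = exprs, channels = ch,
        keywords = keywords, sourcePath = sourcePath)
}

#' Guess channel roles from names
#'
#' Forward/side scatter channels (`FSC*`/`SSC*`) are `"scatter"`, a channel
#' named `Time` is `"time"`, everything else defaults to `"passthrough"`
#' until roles are assigned explicitly (see [assignRoles()]).
#'
#' @param nms character vector of channel names.
#' @return character vector of roles.
#' @export
guessRoles <- function(nms) {
    roles <- rep("passthrough", length(nms))
    roles[grepl("^(FSC|SSC)", nms)] <- "scatter"
    roles[tolower(nms) == "time"] <- "time"
    roles
}

#' Parameters of the logicle scale
#'
#' The logicle display scale is the inverse of a biexponential
#' `B(y) = a e^(b y) - c e^(-d y) - f` that is linear near zero and
#' logarithmic at high intensity. `T` is the top of scale (maps to display
#' position 1), `M` the total display decades, `W` the linearization width in
#' decades and `A` the number of additional negative decades. The remaining
#' coefficient slots are derived at construction time.
#'
#' @slot T,W,M,A the four user-facing parameters.
#' @slot a,b,c,d,f biexponential coefficients.
#' @slot x1 display position of data zero.
#' @seealso [logicleParams()], [logicle()], [inverseLogicle()]
#' @export
setClass("LogicleParams",
    representation(T = "numeric", W = "numeric", M = "numeric", A = "numeric",
                   a = "numeric", b = "numeric", c = "numeric", d = "numeric",
                   f = "numeric", x1 = "numeric")
)

#' Train/validation partition of one capture's events
#'
#' @slot trainIdx,valIdx disjoint integer index vectors covering all events.
#' @slot seed integer seed the partition was drawn with.
#' @slot fraction training fraction in (0, 1).
#' @export
setClass("TrainValSplit",
    representation(trainIdx = "integer", valIdx = "integer",
                   seed = "integer", fraction = "numeric")
)

setValidity("TrainValSplit", function(object) {
    msg <- character()
    if (length(intersect(object@trainIdx, object@valIdx)))
        msg <- c(msg, "train and validation indices must be disjoint")
    n <- length(object@trainIdx) + length(object@valIdx)
    if (!setequal(c(object@trainIdx, object@valIdx), seq_len(n)))
        msg <- c(msg, "indices must cover 1..n exactly once")
    if (length(msg)) msg else TRUE
})

#' A trained backbone-to-marker regression model
#'
#' One gradient-boosted tree model predicting a single exploratory
#' ("Infinity") marker from the backbone channels of one capture, with its
#' held-out validation metrics. Both the mean squared error and the mean
#' absolute error on the validation events are stored.
#'
#' @slot markerName output feature name.
#' @slot sourceFile capture the model was trained on.
#' @slot backboneNames ordered predictor channels (identical across models
#'   of one run).
#' @slot model fitted `xgb.Booster`.
#' @slot split [TrainValSplit-class] used.
#' @slot valMSE,valMAE,valR validation metrics on the regression scale.
#' @slot seed model-level seed.
#' @export
setClass("MarkerModel",
    representation(markerName = "character", sourceFile = "character",
                   backboneNames = "character", model = "ANY",
                   split = "TrainValSplit", valMSE = "numeric",
                   valMAE = "numeric", valR = "numeric", seed = "integer")
)

#' Clustering result
#'
#' @slot labels character cluster label per event; top-level ids are
#'   contiguous `"0"`, `"1"`, ...; sub-cluster labels are namespaced
#'   `"parent.child"`.
#' @slot resolution,nNeighbors,seed parameters used.
#' @slot embedding optional events x 2 UMAP coordinates (0-row matrix if not
#'   computed).
#' @export
setClass("ClusterResult",
    representation(labels = "character", resolution = "numeric",
                   nNeighbors = "integer", seed = "integer",
                   embedding = "matrix")
)

#' Final annotated event-by-feature experiment
#'
#' Extends [SingleCellExperiment::SingleCellExperiment] (features in rows,
#' events in columns). `rowData()` carries the feature `role`
#' (`backbone_transformed`, `imputed`, `passthrough`) and provenance;
#' `colData()` carries `source_file` and `original_event_index` (plus cluster
#' labels once computed); `metadata()` holds the run configuration snapshot
#' and seeds. Features are ordered backbone block, imputed block, passthrough
#' block.
#'
#' @export
setClass("ImputedExperiment", contains = "SingleCellExperiment")

setValidity("ImputedExperiment", function(object) {
    msg <- character()
    rd <- SummarizedExperiment::rowData(object)
    cd <- SummarizedExperiment::colData(object)
    if (!"role" %in% colnames(rd))
        msg <- c(msg, "rowData must have a 'role' column")
    else {
        ok <- c("backbone_transformed", "imputed", "passthrough")
        if (!all(rd$role %in% ok))
            msg <- c(msg, "feature roles must be backbone_transformed, imputed or passthrough")
        # block ordering: backbone, then imputed, then passthrough
        r <- match(rd$role, ok)
        if (is.unsorted(r))
            msg <- c(msg, "features must be ordered backbone, imputed, passthrough")
    }
    if (!all(c("source_file", "original_event_index") %in% colnames(cd)))
        msg <- c(msg, "colData must have source_file and original_event_index")
    if (length(msg)) msg else TRUE
})

#' Generative description of a synthetic Infinity Flow panel
#'
#' Describes a mixture-of-populations backbone model plus exploratory markers
#' defined as known link functions of the backbone with additive Gaussian
#' noise and optional isotype background, from which multi-file FCS panels
#' with ground truth are generated.
#'
#' @slot populationWeights simplex vector of population frequencies.
#' @slot backboneMeans populations x backbone matrix of means (logicle
#'   display scale).
#' @slot backboneCov shared backbone covariance matrix.
#' @slot backboneNames backbone channel names.
#' @slot derivedBackbone list of backbone channels defined as links of the
#'   base channels (used by the surrogate-backbone benchmark).
#' @slot markers list of marker descriptions (name, file, channel, link,
#'   noiseSd, isotypeGroup, isotypeBeta).
#' @slot isotypes list of isotype group definitions (name, link, noiseSd).
#' @slot nEventsPerFile events per generated file.
#' @slot seed master seed.
#' @slot scale `"raw"` (write biexponential raw intensities) or
#'   `"transformed"` (write display-scale values directly).
#' @seealso [syntheticPanelSpec()], [generatePanel()], [attainableR()]
#' @export
setClass("SyntheticPanelSpec",
    representation(populationWeights = "numeric", backboneMeans = "matrix",
                   backboneCov = "matrix", backboneNames = "character",
                   derivedBackbone = "list", markers = "list",
                   isotypes = "list", nEventsPerFile = "integer",
                   seed = "integer", scale = "character")
)

setValidity("SyntheticPanelSpec", function(object) {
    msg <- character()
    w <- object@populationWeights
    if (abs(sum(w) - 1) > 1e-8 || any(w < 0))
        msg <- c(msg, "populationWeights must be non-negative and sum to 1")
    if (nrow(object@backboneMeans) != length(w))
        msg <- c(msg, "backboneMeans must have one row per population")
    ev <- eigen(object@backboneCov, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < -1e-8))
        msg <- c(msg, "backboneCov must be positive semi-definite")
    for (m in object@markers)
        if (!is.null(m$noiseSd) && m$noiseSd < 0)
            msg <- c(msg, "marker noise sd must be >= 0")
    if (!object@scale %in% c("raw", "transformed"))
        msg <- c(msg, "scale must be 'raw' or 'transformed'")
    if (length(msg)) msg else TRUE
})
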