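#' Pool validation events across captures
#'
#' Samples `nPerFile` held-out (validation) events from every capture,
#' without replacement and deterministically per seed, and concatenates them
#' in file order. Files with fewer validation events than requested
#' contribute all of them, with a warning. The pooled events become the
#' prediction substrate of the final object; 10000 per file is the standard
#' design.
#'
#' @param files named list of transformed [EventMatrix-class] objects.
#' @param splits named list of [TrainValSplit-class] per file.
#' @param nPerFile validation events to draw per file (default 10000).
#' @param seed integer seed.
#' @param backboneNames backbone channel names.
#' @param passthrough names of non-backbone channels to carry along; default
#'   is every channel (except exploratory ones) present in all files.
#' @return list with `backbone` (pooled events x backbone matrix),
#'   `passthrough` (pooled events x passthrough matrix), and `eventMeta`
#'   (data.frame of `source_file`, `original_event_index`).
#' @export
poolEvents <- function(files, splits, nPerFile = 10000, seed = 1,
                       backboneNames, passthrough = NULL) {
    stopifnot(is.list(files), !is.null(names(files)),
              all(names(files) %in% names(splits)))
    if (is.null(passthrough)) {
        cand <- lapply(files, function(em) {
            ch <- channels(em)
            ch$short_name[!ch$role %in% c("backbone", "infinity", "isotype")]
        })
        passthrough <- Reduce(intersect, cand)
    }
    bb <- list(); pt <- list(); meta <- list()
    for (fname in names(files)) {
        em <- files[[fname]]
        val <- splits[[fname]]@valIdx
        take <- nPerFile
        if (length(val) < nPerFile) {
            .warnf("file %s has only %d validation events (requested %d); taking all",
                   fname, length(val), nPerFile)
            take <- length(val)
        }
        rs <- .Random.seed.save()
        set.seed(deriveSeed(seed, "pool", fname))
        idx <- if (take < length(val)) sort(sample(val, take)) else val
        .Random.seed.restore(rs)
        bb[[fname]] <- exprs(em)[idx, backboneNames, drop = FALSE]
        pt[[fname]] <- exprs(em)[idx, passthrough, drop = FALSE]
        meta[[fname]] <- data.frame(source_file = fname,
                                    original_event_index = idx)
    }
    list(backbone = do.call(rbind, bb),
         passthrough = do.call(rbind, pt),
         eventMeta = do.call(rbind, c(meta, make.row.names = FALSE)))
}

#' Use a separate reference capture as the prediction substrate
#'
#' All events of the reference file (no sampling) become the backbone the
#' marker models predict onto; its non-backbone channels are carried as
#' passthrough features.
#'
#' @param reference a transformed [EventMatrix-class] containing all
#'   backbone channels.
#' @param backboneNames backbone channel names.
#' @return Same structure as [poolEvents()].
#' @export
useReference <- function(reference, backboneNames) {
    stopifnot(is(reference, "EventMatrix"))
    miss <- setdiff(backboneNames, channelNames(reference))
    if (length(miss))
        .stopf("reference file lacks backbone channel(s): %s",
               paste(miss, collapse = ", "))
    pt <- setdiff(channelNames(reference), backboneNames)
    src <- if (nzchar(reference@sourcePath)) basename(reference@sourcePath)
           else "reference"
    list(backbone = exprs(reference)[, backboneNames, drop = FALSE],
         passthrough = exprs(reference)[, pt, drop = FALSE],
         eventMeta = data.frame(
             source_file = rep(src, nEvents(reference)),
             original_event_index = seq_len(nEvents(reference))))
}

#' Assemble the final annotated experiment
#'
#' Combines the (transformed) backbone block, the imputed marker block and
#' the passthrough block into an [ImputedExperiment-class]
#' (features x events), in that fixed order, with per-event provenance and a
#' run-metadata snapshot. Feature name clashes across blocks are resolved
#' with `make.unique`.
#'
#' @param substrate result of [poolEvents()] or [useReference()].
#' @param imputed events x markers matrix (or `NULL` for none).
#' @param runMeta list of run metadata (config snapshot, seeds, transform
#'   parameters); stored in `metadata()`.
#' @return An [ImputedExperiment-class].
#' @export
buildImputedExperiment <- function(substrate, imputed = NULL,
                                   runMeta = list()) {
    nb <- ncol(substrate$backbone)
    ni <- if (is.null(imputed)) 0L else ncol(imputed)
    np <- ncol(substrate$passthrough)
    X <- cbind(substrate$backbone, imputed, substrate$passthrough)
    roles <- c(rep("backbone_transformed", nb), rep("imputed", ni),
               rep("passthrough", np))
    fn <- make.unique(colnames(X), sep = ".")
    colnames(X) <- fn
    rd <- S4Vectors::DataFrame(role = roles, row.names = fn)
    cd <- S4Vectors::DataFrame(substrate$eventMeta)
    rownames(cd) <- sprintf("event%d", seq_len(nrow(X)))
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(exprs = t(X)), rowData = rd, colData = cd,
        metadata = runMeta)
    new("ImputedExperiment", sce)
}

#' Export the annotated experiment
#'
#' `h5ad` writes an AnnData-compatible HDF5 file (dense `X` events x
#' features, `obs`/`var` data frames, run metadata under `uns`, embeddings
#' under `obsm`). `feather` and `csv` write a flat events x columns frame
#' with event-metadata columns prefixed `meta_`, features in feature order.
#' `h5ad` and `feather` round-trip `X` exactly; `csv` is limited by decimal
#' formatting (15 significant digits).
#'
#' @param object an [ImputedExperiment-class].
#' @param path output path.
#' @param format `"h5ad"`, `"feather"` or `"csv"`.
#' @return `path`, invisibly.
#' @seealso [importAnnotated()]
#' @export
exportAnnotated <- function(object, path,
                            format = c("h5ad", "feather", "csv")) {
    stopifnot(is(object, "ImputedExperiment"))
    format <- match.arg(format)
    if (format == "h5ad") return(.writeH5ad(object, path))
    df <- .flatFrame(object)
    if (format == "feather") arrow::write_feather(df, path)
    else utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

# only plain atomic vectors / nested lists thereof survive into the
# exported run metadata (S4 results such as clustering objects do not)
.serializableMeta <- function(md) {
    keep <- function(x) {
        if (is.atomic(x) && !is.matrix(x)) TRUE
        else if (is.list(x) && !is.object(x)) all(vapply(x, keep, logical(1)))
        else FALSE
    }
    md[vapply(md, keep, logical(1))]
}

.flatFrame <- function(object) {
    X <- t(SummarizedExperiment::assay(object, "exprs"))
    cd <- as.data.frame(SummarizedExperiment::colData(object))
    names(cd) <- paste0("meta_", names(cd))
    cbind(cd, as.data.frame(X), row.names = NULL)
}

.writeH5ad <- function(object, path) {
    if (file.exists(path)) unlink(path)
    X <- SummarizedExperiment::assay(object, "exprs")  # features x events
    cd <- as.data.frame(SummarizedExperiment::colData(object))
    rd <- as.data.frame(SummarizedExperiment::rowData(object))
    md <- S4Vectors::metadata(object)

    h5 <- rhdf5::H5Fcreate(path)
    on.exit(rhdf5::H5Fclose(h5), add = TRUE)
    attrScalar <- function(loc, name, value) {
        rhdf5::h5writeAttribute(value, loc, name, asScalar = TRUE,
                                variableLengthString = TRUE, encoding = "UTF-8")
    }
    rootAttrs <- function(objname, type) {
        o <- rhdf5::H5Oopen(h5, objname)
        attrScalar(o, "encoding-type", type)
        attrScalar(o, "encoding-version",
                   if (type == "dict") "0.1.0" else "0.2.0")
        rhdf5::H5Oclose(o)
    }

    # X: R (features x events) is seen as (events x features) by C-order
    # readers, which is the AnnData obs x var orientation
    rhdf5::h5writeDataset(unname(X), h5, "X")
    rootAttrs("X", "array")

    writeFrame <- function(name, df, index) {
        rhdf5::h5createGroup(h5, name)
        rhdf5::h5writeDataset(index, h5, paste0(name, "/_index"),
                              variableLengthString = TRUE)
        rootAttrs(paste0(name, "/_index"), "string-array")
        for (cn in colnames(df)) {
            v <- df[[cn]]
            if (is.factor(v)) v <- as.character(v)
            rhdf5::h5writeDataset(v, h5, paste0(name, "/", cn),
                                  variableLengthString = is.character(v))
            rootAttrs(paste0(name, "/", cn),
                      if (is.character(v)) "string-array" else "array")
        }
        o <- rhdf5::H5Oopen(h5, name)
        attrScalar(o, "encoding-type", "dataframe")
        attrScalar(o, "encoding-version", "0.2.0")
        attrScalar(o, "_index", "_index")
        rhdf5::h5writeAttribute(colnames(df), o, "column-order",
                                variableLengthString = TRUE,
                                encoding = "UTF-8")
        rhdf5::H5Oclose(o)
    }
    writeFrame("obs", cd, rownames(cd))
    writeFrame("var", rd, rownames(rd))

    rhdf5::h5createGroup(h5, "uns")
    rootAttrs("uns", "dict")
    md <- .serializableMeta(md)
    if (length(md)) {
        rhdf5::h5writeDataset(yaml::as.yaml(md), h5, "uns/run_meta_yaml",
                              variableLengthString = TRUE)
        rootAttrs("uns/run_meta_yaml", "string")
    }

    rds <- SingleCellExperiment::reducedDims(object)
    if (length(rds)) {
        rhdf5::h5createGroup(h5, "obsm")
        rootAttrs("obsm", "dict")
        for (nm in names(rds)) {
            rhdf5::h5writeDataset(unname(t(rds[[nm]])), h5,
                                  paste0("obsm/X_", tolower(nm)))
            rootAttrs(paste0("obsm/X_", tolower(nm)), "array")
        }
    }
    invisible(path)
}

#' Import an exported annotated experiment
#'
#' Reconstructs an [ImputedExperiment-class] from a file written by
#' [exportAnnotated()] (same format).
#'
#' @param path file path.
#' @param format `"h5ad"`, `"feather"` or `"csv"`.
#' @return An [ImputedExperiment-class].
#' @export
importAnnotated <- function(path, format = c("h5ad", "feather", "csv")) {
    format <- match.arg(format)
    if (format == "h5ad") {
        X <- rhdf5::h5read(path, "X")             # features x events in R
        obs <- rhdf5::h5read(path, "obs")
        var <- rhdf5::h5read(path, "var")
        contents <- rhdf5::h5ls(path)
        md <- list()
        if (any(contents$group == "/uns" &
                contents$name == "run_meta_yaml"))
            md <- yaml::yaml.load(rhdf5::h5read(path, "uns/run_meta_yaml"))
        rownames(X) <- as.character(var[["_index"]])
        colnames(X) <- as.character(obs[["_index"]])
        rd <- S4Vectors::DataFrame(role = as.character(var$role),
                                   row.names = rownames(X))
        cdCols <- setdiff(names(obs), "_index")
        cd <- S4Vectors::DataFrame(lapply(obs[cdCols], as.vector),
                                   row.names = colnames(X))
        sce <- SingleCellExperiment::SingleCellExperiment(
            assays = list(exprs = X), rowData = rd, colData = cd,
            metadata = md)
        emb <- contents[contents$group == "/obsm", "name"]
        for (nm in emb) {
            m <- t(rhdf5::h5read(path, paste0("obsm/", nm)))
            SingleCellExperiment::reducedDim(
                sce, toupper(sub("^X_", "", nm))) <- m
        }
        return(new("ImputedExperiment", sce))
    }
    df <- if (format == "feather") as.data.frame(arrow::read_feather(path))
          else utils::read.csv(path, check.names = FALSE)
    metaCols <- grep("^meta_", names(df), value = TRUE)
    featCols <- setdiff(names(df), metaCols)
    X <- as.matrix(df[featCols])
    cd <- df[metaCols]
    names(cd) <- sub("^meta_", "", names(cd))
    roles <- rep("passthrough", length(featCols))
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(exprs = t(X)),
        rowData = S4Vectors::DataFrame(role = roles, row.names = featCols),
        colData = S4Vectors::DataFrame(cd,
            row.names = sprintf("event%d", seq_len(nrow(df)))))
    new("ImputedExperiment", sce)
}
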