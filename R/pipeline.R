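#' Assemble and validate a run configuration
#'
#' Collects everything a pipeline run needs: the capture files, the
#' annotation, the backbone channel list, transform settings, regression
#' hyperparameters, the pooling/reference mode and the seeds. Pooling and
#' reference modes are mutually exclusive; all paths are checked at
#' validation time.
#'
#' @param files named character vector of FCS paths (names become file ids),
#'   or a manifest CSV path with columns `file_id`, `path`.
#' @param annotation annotation data.frame or CSV path with columns `file`,
#'   `infinity_channel`, `marker_name` and optionally `isotype_group`,
#'   `isotype_control`.
#' @param backbone character vector of backbone channel names.
#' @param transform a [transformSpec()]; default logicle with per-channel W
#'   estimation.
#' @param hyperparams list from [boostParams()].
#' @param fraction training fraction (default 0.5).
#' @param nPerFile pooled validation events per file (default 10000).
#' @param referencePath optional backbone reference FCS; switches the run to
#'   reference mode.
#' @param isotypeCorrection apply isotype background correction when the
#'   annotation provides assignments (default `TRUE`).
#' @param minEvents minimum events per capture (default 300).
#' @param seed run seed; every stochastic step derives from it.
#' @return A validated config (class `"FlowRunConfig"`).
#' @export
flowConfig <- function(files, annotation, backbone,
                       transform = transformSpec(),
                       hyperparams = boostParams(), fraction = 0.5,
                       nPerFile = 10000, referencePath = NULL,
                       isotypeCorrection = TRUE, minEvents = 300,
                       seed = 1) {
    if (is.character(files) && length(files) == 1 &&
        grepl("\\.csv$", files)) {
        if (!file.exists(files)) .stopf("manifest not found: %s", files)
        man <- utils::read.csv(files, stringsAsFactors = FALSE)
        files <- stats::setNames(man$path, man$file_id)
    }
    if (is.null(names(files)) || any(!nzchar(names(files))))
        .stopf("'files' must be a named vector (names are file ids)")
    missing <- files[!file.exists(files)]
    if (length(missing))
        .stopf("FCS file(s) not found: %s", paste(missing, collapse = ", "))
    if (is.character(annotation)) {
        if (!file.exists(annotation))
            .stopf("annotation not found: %s", annotation)
        annotation <- utils::read.csv(annotation, stringsAsFactors = FALSE)
    }
    need <- c("file", "infinity_channel", "marker_name")
    if (!all(need %in% colnames(annotation)))
        .stopf("annotation needs columns: %s", paste(need, collapse = ", "))
    if (!is.null(referencePath) && !file.exists(referencePath))
        .stopf("reference FCS not found: %s", referencePath)
    stopifnot(inherits(transform, "TransformSpec"),
              fraction > 0, fraction < 1, nPerFile >= 1)
    structure(list(files = files, annotation = annotation,
                   backbone = backbone, transform = transform,
                   hyperparams = utils::modifyList(boostParams(),
                                                   hyperparams),
                   fraction = fraction, nPerFile = nPerFile,
                   referencePath = referencePath,
                   isotypeCorrection = isTRUE(isotypeCorrection),
                   minEvents = minEvents, seed = as.integer(seed)),
              class = "FlowRunConfig")
}

#' Run the full imputation pipeline
#'
#' Executes read, harmonize, transform, split, fit, validate, predict,
#' optional isotype correction, assembly and optional export as one seeded
#' run. Each stage failure aborts with a stage-named message and removes any
#' partial output file.
#'
#' @param config a [flowConfig()].
#' @param out optional output path; written via [exportAnnotated()].
#' @param format output format when `out` is given.
#' @param verbose log per-stage progress messages (default `TRUE`).
#' @return list with `experiment` (the [ImputedExperiment-class]), `models`,
#'   and `qc` (per-marker validation metrics, background fit report, event
#'   counts, seeds).
#' @export
runPipeline <- function(config, out = NULL,
                        format = c("h5ad", "feather", "csv"),
                        verbose = TRUE) {
    stopifnot(inherits(config, "FlowRunConfig"))
    format <- match.arg(format)
    say <- if (verbose) flogMsg else function(...) invisible()
    stage <- function(name, expr) {
        t0 <- Sys.time()
        r <- tryCatch(expr, error = function(e) {
            if (!is.null(out) && file.exists(out)) unlink(out)
            .stopf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e))
        })
        say(sprintf("stage %-12s %6.2fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
        r
    }

    ann <- config$annotation
    files <- stage("read", {
        fs <- lapply(config$files, readFCS)
        names(fs) <- names(config$files)
        fs
    })
    files <- stage("harmonize", {
        fs <- harmonizeChannels(files, config$backbone)
        for (fname in names(fs)) {
            rows <- ann$file == fname
            if (any(rows))
                fs[[fname]] <- assignRoles(
                    fs[[fname]],
                    unique(as.character(ann$infinity_channel[rows])),
                    isotype = all(.annIsControl(ann)[rows]))
        }
        fs
    })
    trans <- stage("transform", {
        res <- resolveTransforms(config$transform, files)
        list(resolved = res,
             files = lapply(files, applyTransforms, resolved = res))
    })
    resolved <- trans$resolved
    files <- trans$files
    splits <- stage("split", {
        s <- lapply(names(files), function(fname)
            splitEvents(nEvents(files[[fname]]), config$fraction,
                        seed = deriveSeed(config$seed, fname, "split")))
        names(s) <- names(files)
        s
    })
    substrate <- stage("substrate", {
        if (!is.null(config$referencePath)) {
            ref <- readFCS(config$referencePath)
            ref <- harmonizeChannels(list(ref), config$backbone)[[1]]
            ref <- applyTransforms(ref, resolved)
            useReference(ref, config$backbone)
        } else {
            poolEvents(files, splits, nPerFile = config$nPerFile,
                       seed = config$seed, backboneNames = config$backbone)
        }
    })
    fitres <- stage("fit+predict", {
        imputeAll(files, ann, config$backbone,
                  predictionBackbone = substrate$backbone,
                  hyperparams = config$hyperparams,
                  fraction = config$fraction, runSeed = config$seed,
                  minEvents = config$minEvents, splits = splits)
    })
    bgReport <- NULL
    imputed <- fitres$imputed
    if (config$isotypeCorrection) {
        assignments <- isotypeAssignments(ann)
        if (nrow(assignments)) {
            imputed <- stage("background",
                             correctBackground(imputed, assignments))
            bgReport <- attr(imputed, "fitReport")
        }
    }
    experiment <- stage("assemble", {
        runMeta <- list(
            backbone = config$backbone,
            seed = config$seed, fraction = config$fraction,
            nPerFile = config$nPerFile,
            mode = if (is.null(config$referencePath)) "pool" else "reference",
            zscore = isTRUE(config$transform$zscore),
            isotypeCorrection = config$isotypeCorrection,
            hyperparams = config$hyperparams,
            transforms = .describeTransforms(resolved),
            version = as.character(utils::packageVersion("flowImpute")))
        buildImputedExperiment(substrate, imputed, runMeta)
    })
    if (!is.null(out))
        stage("export", exportAnnotated(experiment, out, format))

    qc <- list(
        markers = do.call(rbind, lapply(fitres$models, function(m)
            data.frame(marker = m@markerName, file = m@sourceFile,
                       mse = m@valMSE, mae = m@valMAE, r = m@valR,
                       log10_mse = log10(m@valMSE), seed = m@seed,
                       n_train = length(m@split@trainIdx),
                       n_val = length(m@split@valIdx)))),
        background = bgReport,
        events = vapply(files, nEvents, integer(1)),
        pooled = nrow(substrate$backbone),
        seed = config$seed)
    rownames(qc$markers) <- NULL
    list(experiment = experiment, models = fitres$models, qc = qc)
}

.annIsControl <- function(ann) {
    if ("isotype_control" %in% colnames(ann)) {
        v <- as.logical(ann$isotype_control)
        v[is.na(v)] <- FALSE
        v
    } else rep(FALSE, nrow(ann))
}

# serializable snapshot of resolved per-channel transforms, enabling
# raw-scale recovery from the exported object
.describeTransforms <- function(resolved) {
    lapply(resolved, function(tr) {
        if (tr$kind == "logicle")
            list(kind = "logicle", T = tr$params@T, W = tr$params@W,
                 M = tr$params@M, A = tr$params@A)
        else tr
    })
}
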