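#' Split events into training and validation sets
#'
#' Uniform random partition without replacement, deterministic for a fixed
#' seed. The training size is `round-half-up(fraction * n)`; the default
#' fraction of 0.5 gives the canonical 50/50 train/validation design under
#' which each capture's model is trained on half of its events and scored on
#' the untouched other half.
#'
#' @param n number of events (>= 2).
#' @param fraction training fraction in (0, 1); default 0.5.
#' @param seed integer seed.
#' @return A [TrainValSplit-class].
#' @examples
#' s <- splitEvents(20000, 0.5, seed = 1)
#' length(s@trainIdx)  # 10000
#' @export
splitEvents <- function(n, fraction = 0.5, seed = 1) {
    if (!(is.numeric(n) && n >= 2)) .stopf("splitEvents needs n >= 2")
    if (!(fraction > 0 && fraction < 1))
        .stopf("fraction must be in (0, 1)")
    nTrain <- as.integer(roundHalfUp(fraction * n))
    nTrain <- max(1L, min(as.integer(n) - 1L, nTrain))
    rs <- .Random.seed.save()
    on.exit(.Random.seed.restore(rs))
    set.seed(as.integer(seed))
    trainIdx <- sort(sample.int(n, nTrain))
    new("TrainValSplit", trainIdx = trainIdx,
        valIdx = setdiff(seq_len(as.integer(n)), trainIdx),
        seed = as.integer(seed), fraction = fraction)
}

# keep user RNG state untouched by seeded internals
.Random.seed.save <- function() {
    if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed.restore <- function(rs) {
    if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
}

#' Default regression hyperparameters
#'
#' Gradient-boosted tree settings used for every backbone-to-marker model:
#' squared-error objective, 500 boosting rounds, learning rate 0.05, maximum
#' depth 6, subsample 1.0, single thread (for bit-reproducibility). All are
#' overridable.
#'
#' @param nrounds,eta,max_depth,subsample boosting parameters.
#' @param nthread threads (keep 1 for reproducible training).
#' @return Named list of hyperparameters.
#' @export
boostParams <- function(nrounds = 500, eta = 0.05, max_depth = 6,
                        subsample = 1.0, nthread = 1) {
    list(nrounds = nrounds, eta = eta, max_depth = max_depth,
         subsample = subsample, nthread = nthread)
}

#' Fit one backbone-to-marker regression model
#'
#' Trains a gradient-boosted decision-tree regressor (squared-error
#' objective) of one exploratory marker on the backbone channels.
#' Reproducible given `seed` and `nthread = 1`.
#'
#' @param trainBackbone numeric matrix, training events x backbone channels
#'   (regression scale).
#' @param trainTarget numeric vector of marker values for the same events.
#' @param hyperparams list from [boostParams()].
#' @param seed integer seed for the booster.
#' @param markerName,sourceFile provenance strings.
#' @param split optional [TrainValSplit-class] to attach.
#' @return A [MarkerModel-class] (validation metrics `NA` until
#'   [validateModel()] is applied).
#' @export
fitMarkerModel <- function(trainBackbone, trainTarget,
                           hyperparams = boostParams(), seed = 1,
                           markerName = "marker", sourceFile = "",
                           split = NULL) {
    stopifnot(is.matrix(trainBackbone),
              nrow(trainBackbone) == length(trainTarget))
    if (any(!is.finite(trainBackbone)) || any(!is.finite(trainTarget)))
        .stopf("non-finite values in training data for '%s'", markerName)
    if (stats::sd(trainTarget) == 0)
        .warnf("target '%s' has zero variance; model will predict a constant",
               markerName)
    hp <- utils::modifyList(boostParams(), hyperparams)
    dtrain <- xgboost::xgb.DMatrix(trainBackbone, label = trainTarget,
                                   nthread = hp$nthread)
    booster <- xgboost::xgb.train(
        params = list(objective = "reg:squarederror", eta = hp$eta,
                      max_depth = hp$max_depth, subsample = hp$subsample,
                      nthread = hp$nthread, seed = as.integer(seed)),
        data = dtrain, nrounds = hp$nrounds, verbose = 0)
    if (is.null(split))
        split <- new("TrainValSplit",
                     trainIdx = seq_len(nrow(trainBackbone)),
                     valIdx = integer(0), seed = as.integer(seed),
                     fraction = 1 - 1e-9)
    new("MarkerModel", markerName = markerName, sourceFile = sourceFile,
        backboneNames = colnames(trainBackbone), model = booster,
        split = split, valMSE = NA_real_, valMAE = NA_real_,
        valR = NA_real_, seed = as.integer(seed))
}

#' Predict a marker from backbone values
#'
#' @param model a [MarkerModel-class].
#' @param backbone numeric matrix with the model's backbone channels (matched
#'   by name when column names are present).
#' @return Numeric vector of imputed marker values (regression scale).
#' @export
predictMarker <- function(model, backbone) {
    stopifnot(is(model, "MarkerModel"), is.matrix(backbone))
    if (!is.null(colnames(backbone))) {
        miss <- setdiff(model@backboneNames, colnames(backbone))
        if (length(miss))
            .stopf("backbone matrix lacks channel(s): %s",
                   paste(miss, collapse = ", "))
        backbone <- backbone[, model@backboneNames, drop = FALSE]
    }
    stats::predict(model@model, xgboost::xgb.DMatrix(backbone, nthread = 1))
}

#' Score a model on held-out events
#'
#' Computes the mean squared error and mean absolute error of the model on
#' validation events, on the regression (transformed) scale, plus the Pearson
#' correlation. Both error metrics are kept: MAE is reported alongside MSE
#' (which reporting layers may show on a log10 scale).
#'
#' @param model a [MarkerModel-class].
#' @param valBackbone validation events x backbone channels.
#' @param valTarget measured marker values for those events.
#' @return The model with `valMSE`, `valMAE`, `valR` filled in.
#' @export
validateModel <- function(model, valBackbone, valTarget) {
    if (length(valTarget) == 0 || nrow(valBackbone) == 0)
        .stopf("empty validation set for '%s'", model@markerName)
    pred <- predictMarker(model, valBackbone)
    model@valMSE <- mean((pred - valTarget)^2)
    model@valMAE <- mean(abs(pred - valTarget))
    model@valR <- if (stats::sd(pred) > 0 && stats::sd(valTarget) > 0)
        stats::cor(pred, valTarget) else NA_real_
    model
}

#' Train and impute all annotated markers of a panel
#'
#' For every capture file and each of its annotated exploratory channels,
#' splits the events, trains one backbone-to-marker model on the training
#' half, scores it on the validation half, and predicts the marker for every
#' event of the prediction backbone. Files with k annotated channels yield k
#' models (multi-marker study designs are first-class). Duplicate marker
#' names are deduplicated with `.2`, `.3`, ... suffixes, with a warning.
#'
#' @param files list of harmonized, transformed [EventMatrix-class] objects.
#' @param annotation data.frame with columns `file`, `infinity_channel`,
#'   `marker_name` (one row per marker; `file` matches `names(files)`).
#' @param backboneNames backbone channel names (predictors).
#' @param predictionBackbone events x backbone matrix to impute onto
#'   (pooled validation events or a reference file), or `NULL` to skip
#'   prediction.
#' @param hyperparams list from [boostParams()].
#' @param fraction,runSeed split fraction and run-level seed; each model's
#'   seed is derived by hashing `(runSeed, file, marker)` so adding a file
#'   never perturbs other models.
#' @param minEvents minimum events per file (default 300).
#' @param splits optional named list of precomputed [TrainValSplit-class]
#'   per file.
#' @return list with `models` (list of [MarkerModel-class]) and `imputed`
#'   (matrix of imputed columns, or `NULL`).
#' @export
imputeAll <- function(files, annotation, backboneNames,
                      predictionBackbone = NULL,
                      hyperparams = boostParams(), fraction = 0.5,
                      runSeed = 1, minEvents = 300, splits = NULL) {
    stopifnot(is.list(files),
              all(c("file", "infinity_channel", "marker_name") %in%
                  colnames(annotation)))
    if (is.null(names(files)))
        .stopf("'files' must be a named list matching annotation$file")
    badFiles <- setdiff(annotation$file, names(files))
    if (length(badFiles))
        .stopf("annotation names unknown file(s): %s",
               paste(badFiles, collapse = ", "))

    markerNames <- as.character(annotation$marker_name)
    if (anyDuplicated(markerNames)) {
        .warnf("duplicate marker names deduplicated with suffixes: %s",
               paste(unique(markerNames[duplicated(markerNames)]),
                     collapse = ", "))
        markerNames <- make.unique(markerNames, sep = ".")
    }

    models <- vector("list", nrow(annotation))
    imputed <- if (!is.null(predictionBackbone))
        matrix(NA_real_, nrow(predictionBackbone), nrow(annotation),
               dimnames = list(NULL, markerNames)) else NULL

    for (i in seq_len(nrow(annotation))) {
        fname <- as.character(annotation$file[i])
        chan <- as.character(annotation$infinity_channel[i])
        em <- files[[fname]]
        n <- nEvents(em)
        if (n < minEvents)
            .stopf("file %s has %d events; need at least %d", fname, n,
                   minEvents)
        if (!chan %in% channelNames(em))
            .stopf("annotated exploratory channel '%s' missing from file %s",
                   chan, fname)
        miss <- setdiff(backboneNames, channelNames(em))
        if (length(miss))
            .stopf("file %s lacks backbone channel(s): %s", fname,
                   paste(miss, collapse = ", "))

        split <- if (!is.null(splits)) splits[[fname]] else
            splitEvents(n, fraction,
                        seed = deriveSeed(runSeed, fname, "split"))
        seed <- deriveSeed(runSeed, fname, markerNames[i])
        X <- exprs(em)[, backboneNames, drop = FALSE]
        y <- exprs(em)[, chan]
        model <- fitMarkerModel(X[split@trainIdx, , drop = FALSE],
                                y[split@trainIdx],
                                hyperparams = hyperparams, seed = seed,
                                markerName = markerNames[i],
                                sourceFile = fname, split = split)
        model <- validateModel(model, X[split@valIdx, , drop = FALSE],
                               y[split@valIdx])
        models[[i]] <- model
        if (!is.null(imputed))
            imputed[, i] <- predictMarker(model, predictionBackbone)
    }
    names(models) <- markerNames
    list(models = models, imputed = imputed)
}

#' Surrogate-backbone self-benchmark
#'
#' Ground-truth evaluation of the imputation machinery on truly measured
#' channels: a subset of the backbone is declared the surrogate backbone and
#' used to predict each remaining (held-out) channel, whose measured values
#' then serve as truth. Returns per-channel validation MSE/MAE/r.
#'
#' @param file an [EventMatrix-class] (transformed to the regression scale).
#' @param surrogate channel names used as predictors.
#' @param heldOut channel names to predict; must be disjoint from
#'   `surrogate`.
#' @param hyperparams list from [boostParams()].
#' @param fraction,seed split settings.
#' @return data.frame with one row per held-out channel: `channel`, `mse`,
#'   `mae`, `r`, plus the fitted models as attribute `"models"`.
#' @export
surrogateBackboneEval <- function(file, surrogate, heldOut,
                                  hyperparams = boostParams(),
                                  fraction = 0.5, seed = 1) {
    stopifnot(is(file, "EventMatrix"))
    if (length(intersect(surrogate, heldOut)))
        .stopf("surrogate and held-out channel sets overlap: %s",
               paste(intersect(surrogate, heldOut), collapse = ", "))
    miss <- setdiff(c(surrogate, heldOut), channelNames(file))
    if (length(miss))
        .stopf("channel(s) not in file: %s", paste(miss, collapse = ", "))

    n <- nEvents(file)
    X <- exprs(file)[, surrogate, drop = FALSE]
    models <- list()
    res <- lapply(heldOut, function(ch) {
        split <- splitEvents(n, fraction, seed = deriveSeed(seed, ch, "split"))
        y <- exprs(file)[, ch]
        m <- fitMarkerModel(X[split@trainIdx, , drop = FALSE],
                            y[split@trainIdx], hyperparams = hyperparams,
                            seed = deriveSeed(seed, ch),
                            markerName = ch, sourceFile = file@sourcePath,
                            split = split)
        m <- validateModel(m, X[split@valIdx, , drop = FALSE],
                           y[split@valIdx])
        models[[ch]] <<- m
        data.frame(channel = ch, mse = m@valMSE, mae = m@valMAE, r = m@valR)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    attr(out, "models") <- models
    out
}
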