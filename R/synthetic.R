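#' Link function constructors for synthetic markers
#'
#' Synthetic exploratory markers are known functions of the backbone plus
#' Gaussian noise. Three link families span easy to hard regression regimes:
#' linear combinations, switch-like logistic responses, and products of two
#' channels (pure interaction, invisible to additive models).
#'
#' @param channels backbone channel name(s) the link reads.
#' @param coefs,intercept linear coefficients and offset.
#' @param channel single channel for the logistic link.
#' @param amp,mid,k logistic amplitude, midpoint and steepness.
#' @param coef interaction coefficient.
#' @return A link specification list, for [syntheticPanelSpec()] markers.
#' @name links
NULL

#' @rdname links
#' @export
linkLinear <- function(channels, coefs, intercept = 0) {
    stopifnot(length(channels) == length(coefs))
    list(type = "linear", channels = channels, coefs = coefs,
         intercept = intercept)
}

#' @rdname links
#' @export
linkLogistic <- function(channel, amp = 0.5, mid = 0.5, k = 12) {
    list(type = "logistic", channels = channel, amp = amp, mid = mid, k = k)
}

#' @rdname links
#' @export
linkInteraction <- function(channels, coef = 1, intercept = 0) {
    stopifnot(length(channels) == 2)
    list(type = "interaction", channels = channels, coef = coef,
         intercept = intercept)
}

#' Evaluate a link function over a backbone matrix
#'
#' @param link a link spec from [linkLinear()], [linkLogistic()] or
#'   [linkInteraction()].
#' @param backbone events x channels matrix with named columns.
#' @return Numeric vector of noiseless link values.
#' @export
evalLink <- function(link, backbone) {
    miss <- setdiff(link$channels, colnames(backbone))
    if (length(miss))
        .stopf("link references unknown channel(s): %s",
               paste(miss, collapse = ", "))
    B <- backbone[, link$channels, drop = FALSE]
    switch(link$type,
        linear = as.vector(B %*% link$coefs) + link$intercept,
        logistic = link$amp / (1 + exp(-link$k * (B[, 1] - link$mid))),
        interaction = link$coef * B[, 1] * B[, 2] + link$intercept,
        .stopf("unknown link type '%s'", link$type))
}

#' Construct a synthetic panel specification
#'
#' Describes a complete Infinity Flow style study: a mixture of Gaussian
#' populations over the backbone channels (on the logicle display scale,
#' where the link + additive noise model is exact), exploratory markers as
#' link functions of the backbone, isotype background processes, and the
#' per-file event count. `generatePanel()` materializes it as FCS files with
#' ground-truth tables.
#'
#' @param backboneMeans populations x backbone matrix (display scale,
#'   typically within 0.1-0.9); column names become backbone channel names.
#' @param populationWeights population frequencies (summing to 1); default
#'   uniform.
#' @param backboneCov shared covariance; default diagonal with sd 0.05.
#' @param derivedBackbone list of backbone channels defined as links of the
#'   base channels: each `list(name=, link=, noiseSd=)`.
#' @param markers list of marker specs: each
#'   `list(name=, link=, noiseSd=, file=, channel=, isotypeGroup=,
#'   isotypeBeta=)`; `file` defaults to the marker name, `channel` to
#'   `"PE"`, `isotypeBeta` to 0.
#' @param isotypes list of isotype background processes:
#'   `list(name=, link=, noiseSd=)` (the group's control capture measures
#'   `link(backbone) + noise`).
#' @param nEventsPerFile events per capture; default 20000, matching the
#'   at-least-20000-events study design.
#' @param seed master seed; everything derives from it.
#' @param scale `"raw"`: write `inverseLogicle(display)` raw intensities
#'   (files then need the matching fixed logicle transform, see
#'   [panelLogicleSpec()]); `"transformed"`: write display values directly
#'   (use a linear transform).
#' @return A [SyntheticPanelSpec-class].
#' @export
syntheticPanelSpec <- function(backboneMeans,
                               populationWeights =
                                   rep(1 / nrow(backboneMeans),
                                       nrow(backboneMeans)),
                               backboneCov = diag(0.05^2,
                                                  ncol(backboneMeans)),
                               derivedBackbone = list(), markers = list(),
                               isotypes = list(),
                               nEventsPerFile = 20000L, seed = 1L,
                               scale = c("raw", "transformed")) {
    scale <- match.arg(scale)
    stopifnot(!is.null(colnames(backboneMeans)))
    markers <- lapply(markers, function(m) {
        if (is.null(m$file)) m$file <- m$name
        if (is.null(m$channel)) m$channel <- "PE"
        if (is.null(m$isotypeBeta)) m$isotypeBeta <- 0
        if (is.null(m$isotypeGroup)) m$isotypeGroup <- NA_character_
        m
    })
    new("SyntheticPanelSpec",
        populationWeights = populationWeights,
        backboneMeans = backboneMeans, backboneCov = backboneCov,
        backboneNames = colnames(backboneMeans),
        derivedBackbone = derivedBackbone, markers = markers,
        isotypes = isotypes, nEventsPerFile = as.integer(nEventsPerFile),
        seed = as.integer(seed), scale = scale)
}

#' The logicle parameters a raw-scale synthetic panel was generated under
#'
#' Raw-scale panels are written as `inverseLogicle(display)` with this fixed
#' parameterization (`T = 262144, W = 0.5, M = 4.5, A = 0`); running the
#' pipeline with the same fixed transform recovers the generative display
#' scale exactly, so injected noise variances apply unchanged on the
#' regression scale.
#'
#' @return A [transformSpec()] with the fixed logicle parameters.
#' @export
panelLogicleSpec <- function() transformSpec("logicle", T = 262144, W = 0.5,
                                             M = 4.5, A = 0)

# draw the latent display-scale event table for one capture
.simEvents <- function(spec, n, seed) {
    rs <- .Random.seed.save()
    on.exit(.Random.seed.restore(rs))
    set.seed(seed)
    nPop <- length(spec@populationWeights)
    pop <- sample.int(nPop, n, replace = TRUE,
                      prob = spec@populationWeights)
    L <- chol(spec@backboneCov + diag(1e-12, ncol(spec@backboneCov)))
    B <- spec@backboneMeans[pop, , drop = FALSE] +
        matrix(stats::rnorm(n * ncol(L)), n) %*% L
    colnames(B) <- spec@backboneNames
    for (d in spec@derivedBackbone) {
        v <- evalLink(d$link, B) + stats::rnorm(n, sd = d$noiseSd)
        B <- cbind(B, v)
        colnames(B)[ncol(B)] <- d$name
    }
    bg <- lapply(spec@isotypes, function(iso) evalLink(iso$link, B))
    names(bg) <- vapply(spec@isotypes, `[[`, character(1), "name")
    # scatter and time channels carried as passthrough by the pipeline
    fsc <- stats::rlnorm(n, log(5e4), 0.3)
    ssc <- stats::rlnorm(n, log(3e4), 0.4)
    tm <- cumsum(stats::runif(n, 0.1, 1))
    list(pop = pop, backbone = B, bg = bg, fsc = fsc, ssc = ssc, time = tm)
}

.displayToStored <- function(x, spec, lp) {
    if (spec@scale == "raw") inverseLogicle(x, lp) else x
}

#' Generate a synthetic Infinity Flow panel on disk
#'
#' Writes one FCS file per capture (markers grouped by their `file` field,
#' so multi-marker captures are supported), one isotype-control FCS file per
#' isotype group, an annotation CSV (`file`, `infinity_channel`,
#' `marker_name`, `isotype_group`, `isotype_control`), per-file ground-truth
#' TSVs (population label, noiseless marker values, background values), and
#' optionally a backbone-only reference file. Fully deterministic per seed:
#' the same spec yields byte-identical files.
#'
#' Each marker channel is `link(backbone) + Normal(0, noiseSd) +
#' isotypeBeta * background(backbone)`; each isotype-control channel is
#' `background(backbone) + Normal(0, noiseSd)`.
#'
#' @param spec a [SyntheticPanelSpec-class].
#' @param outDir output directory (created if needed).
#' @param reference also write `reference.fcs` holding backbone channels
#'   only (default `FALSE`).
#' @return Invisibly, a list with `files` (named FCS paths), `annotation`
#'   (data.frame and `annotationPath`), `truth` (named TSV paths) and
#'   `referencePath` (or `NA`).
#' @export
generatePanel <- function(spec, outDir, reference = FALSE) {
    stopifnot(is(spec, "SyntheticPanelSpec"))
    validObject(spec)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    lp <- logicleParams(262144, 0.5, 4.5, 0)
    n <- spec@nEventsPerFile

    isoNames <- vapply(spec@isotypes, `[[`, character(1), "name")
    markerFiles <- unique(vapply(spec@markers, `[[`, character(1), "file"))

    ann <- list(); files <- character(); truthPaths <- character()

    writeCapture <- function(fname, markersInFile, isoGroup = NULL) {
        ev <- .simEvents(spec, n, deriveSeed(spec@seed, "file", fname))
        B <- ev$backbone
        rs <- .Random.seed.save()
        on.exit(.Random.seed.restore(rs))
        set.seed(deriveSeed(spec@seed, "noise", fname))
        drawNoise <- function(sd) stats::rnorm(n, sd = sd)
        truth <- data.frame(population = ev$pop)
        extraCols <- list(); extraNames <- character()
        for (m in markersInFile) {
            sig <- evalLink(m$link, B)
            y <- sig + drawNoise(m$noiseSd)
            if (!is.na(m$isotypeGroup) && m$isotypeBeta != 0) {
                if (!m$isotypeGroup %in% names(ev$bg))
                    .stopf("marker '%s' references unknown isotype group '%s'",
                           m$name, m$isotypeGroup)
                y <- y + m$isotypeBeta * ev$bg[[m$isotypeGroup]]
            }
            extraCols[[length(extraCols) + 1]] <- y
            extraNames <- c(extraNames, m$channel)
            truth[[paste0("true_", m$name)]] <- sig
        }
        if (!is.null(isoGroup)) {
            iso <- spec@isotypes[[match(isoGroup, isoNames)]]
            y <- ev$bg[[isoGroup]] + drawNoise(iso$noiseSd)
            extraCols[[length(extraCols) + 1]] <- y
            extraNames <- c(extraNames, "PE")
            truth[[paste0("bg_", isoGroup)]] <- ev$bg[[isoGroup]]
        }
        for (g in names(ev$bg)) {
            cn <- paste0("bg_", g)
            if (!cn %in% colnames(truth)) truth[[cn]] <- ev$bg[[g]]
        }
        X <- cbind(.displayToStored(B, spec, lp),
                   if (length(extraCols))
                       .displayToStored(do.call(cbind, extraCols), spec, lp),
                   ev$fsc, ev$ssc, ev$time)
        colnames(X) <- c(colnames(B), extraNames, "FSC-A", "SSC-A", "Time")
        em <- eventMatrix(X, keywords = c("$CYT" = "flowImpute synthetic"))
        fpath <- file.path(outDir, paste0(fname, ".fcs"))
        writeFCS(em, fpath)
        tpath <- file.path(outDir, paste0(fname, "_truth.tsv"))
        utils::write.table(truth, tpath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        files[fname] <<- fpath
        truthPaths[fname] <<- tpath
    }

    for (fname in markerFiles) {
        inFile <- Filter(function(m) m$file == fname, spec@markers)
        writeCapture(fname, inFile)
        for (m in inFile)
            ann[[length(ann) + 1]] <- data.frame(
                file = fname, infinity_channel = m$channel,
                marker_name = m$name, isotype_group = m$isotypeGroup,
                isotype_control = FALSE)
    }
    for (g in isoNames) {
        fname <- paste0("isotype_", g)
        writeCapture(fname, list(), isoGroup = g)
        ann[[length(ann) + 1]] <- data.frame(
            file = fname, infinity_channel = "PE",
            marker_name = paste0("Isotype_", g), isotype_group = g,
            isotype_control = TRUE)
    }

    refPath <- NA_character_
    if (reference) {
        ev <- .simEvents(spec, n, deriveSeed(spec@seed, "file", "reference"))
        X <- cbind(.displayToStored(ev$backbone, spec, lp),
                   ev$fsc, ev$ssc, ev$time)
        colnames(X) <- c(colnames(ev$backbone), "FSC-A", "SSC-A", "Time")
        refPath <- file.path(outDir, "reference.fcs")
        writeFCS(eventMatrix(X, keywords = c("$CYT" = "flowImpute synthetic")),
                 refPath)
    }

    annotation <- if (length(ann)) do.call(rbind, ann) else
        data.frame(file = character(), infinity_channel = character(),
                   marker_name = character(), isotype_group = character(),
                   isotype_control = logical())
    annPath <- file.path(outDir, "annotation.csv")
    utils::write.csv(annotation, annPath, row.names = FALSE)
    invisible(list(files = files, annotation = annotation,
                   annotationPath = annPath, truth = truthPaths,
                   referencePath = refPath))
}

#' Theoretical attainable correlation for a synthetic marker
#'
#' The best possible Pearson correlation between any function of the
#' backbone and the noisy marker is `sd(link) / sqrt(sd(link)^2 +
#' noiseSd^2)`; `sd(link)` is estimated by Monte-Carlo from the generator.
#' Applies to markers and to derived backbone channels, and serves as the
#' yardstick for imputation recovery tests.
#'
#' @param spec a [SyntheticPanelSpec-class].
#' @param name marker (or derived backbone channel) name.
#' @param nMC Monte-Carlo sample size.
#' @return The attainable correlation in `[0, 1]`.
#' @export
attainableR <- function(spec, name, nMC = 100000) {
    stopifnot(is(spec, "SyntheticPanelSpec"))
    entry <- NULL
    for (m in spec@markers) if (m$name == name) entry <- m
    if (is.null(entry))
        for (d in spec@derivedBackbone) if (d$name == name) entry <- d
    if (is.null(entry)) .stopf("no marker or derived channel named '%s'", name)
    ev <- .simEvents(spec, nMC, deriveSeed(spec@seed, "attainableR", name))
    sig <- evalLink(entry$link, ev$backbone)
    if (!is.null(entry$isotypeGroup) && !is.na(entry$isotypeGroup) &&
        !is.null(entry$isotypeBeta) && entry$isotypeBeta != 0)
        sig <- sig + entry$isotypeBeta * ev$bg[[entry$isotypeGroup]]
    s <- stats::sd(sig)
    s / sqrt(s^2 + entry$noiseSd^2)
}

#' Ready-made example panel specification
#'
#' A small multi-capture study: `nMarkers` exploratory markers (cycling
#' through linear, logistic and interaction links) over `nBackbone` backbone
#' channels and `nPopulations` Gaussian populations, with one shared isotype
#' background process. Defaults mirror a desk-scale capture design of 20000
#' events per file.
#'
#' @param nMarkers,nBackbone,nPopulations panel dimensions.
#' @param nEventsPerFile events per capture.
#' @param seed master seed.
#' @param noiseSd marker noise sd (display scale).
#' @param isotypeBetas per-marker background slopes (recycled), or `NULL`
#'   (default) for a panel without isotype controls. When given, every
#'   marker is assigned to the shared `IgG1` isotype group, including
#'   markers with a slope of 0 (so a zero planted slope is itself
#'   recoverable).
#' @param scale see [syntheticPanelSpec()].
#' @return A [SyntheticPanelSpec-class].
#' @export
examplePanelSpec <- function(nMarkers = 3, nBackbone = 7, nPopulations = 4,
                             nEventsPerFile = 20000, seed = 1,
                             noiseSd = 0.05, isotypeBetas = NULL,
                             scale = "raw") {
    rs <- .Random.seed.save()
    on.exit(.Random.seed.restore(rs))
    set.seed(deriveSeed(seed, "examplePanelSpec"))
    bbNames <- sprintf("BB%02d", seq_len(nBackbone))
    means <- matrix(stats::runif(nPopulations * nBackbone, 0.25, 0.8),
                    nPopulations, nBackbone, dimnames = list(NULL, bbNames))
    # BB01 drives the isotype background: its mean is constant across
    # populations (nonspecific binding independent of lineage), which keeps
    # planted background slopes identifiable by the linear correction
    means[, 1] <- 0.5
    w <- stats::runif(nPopulations, 0.5, 1.5); w <- w / sum(w)
    hasIso <- !is.null(isotypeBetas)
    isotypeBetas <- if (hasIso) rep_len(isotypeBetas, nMarkers) else
        rep(0, nMarkers)
    markers <- lapply(seq_len(nMarkers), function(i) {
        chs <- sample(bbNames[-1], 2)
        link <- switch((i - 1) %% 3 + 1,
            linkLinear(chs, c(0.6, 0.4), intercept = 0.05),
            linkLogistic(chs[1], amp = 0.5, mid = 0.5, k = 12),
            linkInteraction(chs, coef = 1.2, intercept = 0.05))
        list(name = sprintf("Marker%02d", i), link = link,
             noiseSd = noiseSd,
             isotypeGroup = if (hasIso) "IgG1" else NA_character_,
             isotypeBeta = isotypeBetas[i])
    })
    isotypes <- if (hasIso)
        list(list(name = "IgG1",
                  link = linkLogistic(bbNames[1], amp = 1, mid = 0.5,
                                      k = 8),
                  noiseSd = 0.03)) else list()
    syntheticPanelSpec(means, populationWeights = w,
                       backboneCov = diag(0.05^2, nBackbone),
                       markers = markers, isotypes = isotypes,
                       nEventsPerFile = nEventsPerFile, seed = seed,
                       scale = scale)
}

#' Surrogate-backbone benchmark panel specification
#'
#' A 21-channel backbone in which the first `nBase` channels are a Gaussian
#' population mixture and the remaining `nDerived` channels are known link
#' functions of the base channels plus noise — the design used to
#' self-benchmark imputation by predicting truly measured channels from a
#' surrogate backbone (11 predicting 10 by default).
#'
#' @param nBase,nDerived base and derived backbone channel counts.
#' @param nEventsPerFile events in the capture.
#' @param seed master seed.
#' @param noiseSd derived-channel noise sd (display scale).
#' @param scale see [syntheticPanelSpec()].
#' @return A [SyntheticPanelSpec-class]; generate with
#'   `generatePanel(spec, dir, reference = TRUE)` and evaluate with
#'   [surrogateBackboneEval()] on `reference.fcs`.
#' @export
surrogatePanelSpec <- function(nBase = 11, nDerived = 10,
                               nEventsPerFile = 20000, seed = 1,
                               noiseSd = 0.05, scale = "raw") {
    rs <- .Random.seed.save()
    on.exit(.Random.seed.restore(rs))
    set.seed(deriveSeed(seed, "surrogatePanelSpec"))
    nPop <- 5
    baseNames <- sprintf("BB%02d", seq_len(nBase))
    means <- matrix(stats::runif(nPop * nBase, 0.25, 0.8), nPop, nBase,
                    dimnames = list(NULL, baseNames))
    w <- stats::runif(nPop, 0.5, 1.5); w <- w / sum(w)
    derived <- lapply(seq_len(nDerived), function(i) {
        chs <- sample(baseNames, 2)
        link <- switch((i - 1) %% 3 + 1,
            linkLinear(chs, c(0.55, 0.35), intercept = 0.05),
            linkLogistic(chs[1], amp = 0.5, mid = 0.5, k = 12),
            linkInteraction(chs, coef = 1.1, intercept = 0.05))
        list(name = sprintf("BB%02d", nBase + i), link = link,
             noiseSd = noiseSd)
    })
    syntheticPanelSpec(means, populationWeights = w,
                       backboneCov = diag(0.05^2, nBase),
                       derivedBackbone = derived,
                       nEventsPerFile = nEventsPerFile, seed = seed,
                       scale = scale)
}
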