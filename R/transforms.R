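#' Construct logicle scale parameters
#'
#' Derives the biexponential coefficients from the four user-facing logicle
#' parameters. The display scale maps raw intensity `T` to position 1 and
#' data zero to position `x1 = (A + W)/(M + A)`, with a quasi-linear region
#' of width `W` decades around zero and pure-log behaviour at high intensity.
#'
#' Coefficients follow the published parameterization: with
#' `w = W/(M+A)`, `b = (M+A) ln 10`, `d` solves
#' `2(ln d - ln b) + w(b + d) = 0`, and `a`, `c`, `f` are fixed by
#' `B(1) = T` and `B(x1) = 0`. For display positions below `x1` the scale is
#' continued by odd symmetry about `(x1, 0)`, as in the reference logicle
#' implementation.
#'
#' @param T top of scale (> 0); default 262144.
#' @param W linearization width in decades, `0 <= W <= M/2`; default 0.5.
#' @param M total display decades (> 0); default 4.5.
#' @param A additional negative display decades, `0 <= A <= M - 2W`;
#'   default 0.
#' @return A [LogicleParams-class] object.
#' @examples
#' p <- logicleParams()
#' logicle(262144, p)        # 1: top of scale
#' inverseLogicle(1, p)      # back to 262144
#' @export
logicleParams <- function(T = 262144, W = 0.5, M = 4.5, A = 0) {
    if (!(is.finite(T) && T > 0)) .stopf("logicle: T must be > 0")
    if (!(is.finite(M) && M > 0)) .stopf("logicle: M must be > 0")
    if (!(is.finite(W) && W >= 0 && W <= M / 2))
        .stopf("logicle: W must satisfy 0 <= W <= M/2 (got W=%g, M=%g)", W, M)
    if (!(is.finite(A) && A >= 0 && A <= M - 2 * W))
        .stopf("logicle: A must satisfy 0 <= A <= M - 2W (got A=%g)", A)

    w <- W / (M + A)
    x2 <- A / (M + A)
    x1 <- x2 + w
    x0 <- x2 + 2 * w
    b <- (M + A) * log(10)
    d <- if (w == 0) b else {
        # root of 2(ln d - ln b) + w(b + d) = 0 on (0, b]
        stats::uniroot(function(d) 2 * (log(d) - log(b)) + w * (b + d),
                       lower = b * 1e-12, upper = b, tol = 1e-14)$root
    }
    c_a <- exp(x0 * (b + d))
    mf_a <- exp(b * x1) - c_a / exp(d * x1)
    a <- T / (exp(b) - mf_a - c_a / exp(d))
    new("LogicleParams", T = T, W = W, M = M, A = A,
        a = a, b = b, c = c_a * a, d = d, f = -mf_a * a, x1 = x1)
}

#' Biexponential (inverse logicle) in closed form
#'
#' Maps display-scale positions back to raw intensity:
#' `B(y) = a e^(b y) - c e^(-d y) + f` for `y >= x1`, continued by odd
#' symmetry (`-B(2 x1 - y)`) below `x1`. Strictly increasing.
#'
#' @param y numeric vector of display positions.
#' @param p a [LogicleParams-class] (or the arguments of [logicleParams()]).
#' @return Raw-scale values.
#' @export
inverseLogicle <- function(y, p = logicleParams()) {
    stopifnot(is(p, "LogicleParams"))
    neg <- y < p@x1
    yy <- ifelse(neg, 2 * p@x1 - y, y)
    v <- p@a * exp(p@b * yy) - p@c * exp(-p@d * yy) + p@f
    ifelse(neg, -v, v)
}

#' Logicle transform
#'
#' Numerical inverse of the biexponential: returns `y` with
#' `inverseLogicle(y, p) = x`, converged to `|B(y) - x| <= T * 1e-10`
#' (safeguarded Newton iteration within a bisection bracket). Strictly
#' increasing in `x`; `logicle(T) = 1` and `logicle(0) = x1`.
#'
#' @param x numeric vector of raw intensities (negatives allowed).
#' @param p a [LogicleParams-class].
#' @return Display-scale values.
#' @export
logicle <- function(x, p = logicleParams()) {
    stopifnot(is(p, "LogicleParams"))
    out <- numeric(length(x))
    neg <- x < 0
    out[!neg] <- .logiclePositive(x[!neg], p)
    if (any(neg)) out[neg] <- 2 * p@x1 - .logiclePositive(-x[neg], p)
    out
}

# solve B(y) = x for x >= 0 (so y >= x1), vectorized
.logiclePositive <- function(x, p) {
    n <- length(x)
    if (n == 0) return(numeric(0))
    tol <- p@T * 1e-10
    biexp <- function(y) p@a * exp(p@b * y) - p@c * exp(-p@d * y) + p@f
    dbiexp <- function(y) p@a * p@b * exp(p@b * y) + p@c * p@d * exp(-p@d * y)
    hi0 <- 1.5
    while (biexp(hi0) < max(x)) hi0 <- hi0 + 0.5
    lo <- rep(p@x1, n); hi <- rep(hi0, n)
    y <- (lo + hi) / 2
    for (it in seq_len(100)) {
        fy <- biexp(y) - x
        if (all(abs(fy) <= tol)) break
        lo <- ifelse(fy < 0, y, lo)
        hi <- ifelse(fy > 0, y, hi)
        yn <- y - fy / dbiexp(y)
        mid <- (lo + hi) / 2
        y <- ifelse(is.finite(yn) & yn > lo & yn < hi, yn, mid)
    }
    y
}

#' Estimate the logicle linearization width from data
#'
#' Uses the standard heuristic `W = (M - log10(T / |r|)) / 2` with `r` the
#' 5th percentile of the negative events, clamped to `[0.25, M/2]`. Returns
#' the default `W = 0.5` when the channel has no negative events.
#'
#' @param x numeric vector of raw channel values.
#' @param T,M logicle top of scale and decades.
#' @param default W when no negative events exist.
#' @return Estimated `W`.
#' @export
estimateLogicleW <- function(x, T = 262144, M = 4.5, default = 0.5) {
    negs <- x[x < 0]
    if (length(negs) == 0) return(default)
    r <- stats::quantile(negs, 0.05, names = FALSE)
    W <- (M - log10(T / abs(r))) / 2
    min(max(W, 0.25), M / 2)
}

#' Arcsinh transform
#'
#' Elementwise `asinh(x / cofactor)`, the standard alternative display scale
#' for cytometry data.
#'
#' @param x numeric vector.
#' @param cofactor positive scale divisor (default 150, a common choice for
#'   conventional flow).
#' @return Transformed vector.
#' @export
arcsinhTransform <- function(x, cofactor = 150) {
    if (!(is.numeric(cofactor) && length(cofactor) == 1 && cofactor > 0))
        .stopf("arcsinh cofactor must be a positive number")
    asinh(x / cofactor)
}

#' Z-score normalization
#'
#' Centers and scales to unit variance using the sample standard deviation
#' (n - 1 denominator). Intended per channel per source file to damp batch
#' effects, but OFF by default throughout the pipeline: per-file
#' standardization distorts the backbone-to-marker mapping whenever files
#' differ in population composition, injecting artifacts into the imputed
#' values (see the package vignette).
#'
#' @param x numeric vector, length >= 2.
#' @return `(x - mean(x)) / sd(x)`; all zeros with a warning when the input
#'   is constant.
#' @export
zscoreNormalize <- function(x) {
    if (length(x) < 2) .stopf("zscoreNormalize needs at least 2 values")
    s <- stats::sd(x)
    if (s == 0) {
        .warnf("zscoreNormalize: constant input, returning zeros")
        return(rep(0, length(x)))
    }
    (x - mean(x)) / s
}

#' Transform specification
#'
#' Describes how raw channel values are mapped to the regression scale.
#' Fluorescence channels get the chosen `kind`; scatter and time channels are
#' always left linear. `W = NA` requests per-channel estimation from data
#' (pooled across files) via [estimateLogicleW()].
#'
#' @param kind `"logicle"` (default), `"arcsinh"` or `"linear"`.
#' @param T,W,M,A logicle parameters (see [logicleParams()]).
#' @param cofactor arcsinh cofactor.
#' @param perChannel named list of per-channel overrides, each itself a list
#'   with any of `kind`, `T`, `W`, `M`, `A`, `cofactor`.
#' @param zscore apply per-file z-score normalization after the transform
#'   (default `FALSE`; see [zscoreNormalize()]).
#' @return A list of class `"TransformSpec"`.
#' @export
transformSpec <- function(kind = c("logicle", "arcsinh", "linear"),
                          T = 262144, W = NA, M = 4.5, A = 0,
                          cofactor = 150, perChannel = list(),
                          zscore = FALSE) {
    kind <- match.arg(kind)
    structure(list(kind = kind, T = T, W = W, M = M, A = A,
                   cofactor = cofactor, perChannel = perChannel,
                   zscore = isTRUE(zscore)),
              class = "TransformSpec")
}

#' Resolve a transform spec against a set of files
#'
#' Fixes one effective transform per channel: scatter/time channels are
#' linear; others follow the spec with per-channel overrides; a logicle
#' `W = NA` is estimated once per channel from the data pooled across all
#' files, so every file shares identical channel scales.
#'
#' @param spec a [transformSpec()].
#' @param files list of (harmonized) [EventMatrix-class] objects.
#' @return Named list (by channel) of resolved transforms, class
#'   `"ResolvedTransforms"`; each element has `kind` and its parameters.
#' @export
resolveTransforms <- function(spec, files) {
    stopifnot(inherits(spec, "TransformSpec"), length(files) >= 1)
    allCh <- unique(unlist(lapply(files, channelNames)))
    roles <- list()
    for (em in files) {
        r <- channelRoles(em)
        roles[names(r)] <- r
    }
    res <- lapply(allCh, function(ch) {
        role <- roles[[ch]]
        if (role %in% c("scatter", "time")) return(list(kind = "linear"))
        ov <- spec$perChannel[[ch]]
        kind <- if (!is.null(ov$kind)) ov$kind else spec$kind
        if (kind == "linear") return(list(kind = "linear"))
        if (kind == "arcsinh") {
            cf <- if (!is.null(ov$cofactor)) ov$cofactor else spec$cofactor
            return(list(kind = "arcsinh", cofactor = cf))
        }
        T <- if (!is.null(ov$T)) ov$T else spec$T
        W <- if (!is.null(ov$W)) ov$W else spec$W
        M <- if (!is.null(ov$M)) ov$M else spec$M
        A <- if (!is.null(ov$A)) ov$A else spec$A
        if (is.na(W)) {
            pooled <- unlist(lapply(files, function(em) {
                if (ch %in% channelNames(em)) exprs(em)[, ch] else NULL
            }))
            W <- estimateLogicleW(pooled, T = T, M = M)
        }
        list(kind = "logicle", params = logicleParams(T, W, M, A))
    })
    names(res) <- allCh
    structure(res, class = "ResolvedTransforms", zscore = spec$zscore)
}

#' Apply resolved transforms to one capture
#'
#' Transforms every channel of an [EventMatrix-class] to the regression
#' scale. When `zscore = TRUE`, non-scatter/time channels are additionally
#' z-scored per file after the transform (the configuration the package
#' warns against; see [zscoreNormalize()]).
#'
#' @param object an [EventMatrix-class].
#' @param resolved a [resolveTransforms()] result.
#' @param zscore override the spec's z-score flag; default taken from
#'   `resolved`.
#' @return The [EventMatrix-class] with transformed values.
#' @export
applyTransforms <- function(object, resolved,
                            zscore = attr(resolved, "zscore")) {
    stopifnot(is(object, "EventMatrix"),
              inherits(resolved, "ResolvedTransforms"))
    x <- object@exprs
    roles <- object@channels$role
    for (j in seq_len(ncol(x))) {
        ch <- colnames(x)[j]
        tr <- resolved[[ch]]
        if (is.null(tr))
            .stopf("no resolved transform for channel '%s'", ch)
        x[, j] <- switch(tr$kind,
            linear = x[, j],
            arcsinh = arcsinhTransform(x[, j], tr$cofactor),
            logicle = logicle(x[, j], tr$params))
        if (isTRUE(zscore) && !roles[j] %in% c("scatter", "time") &&
            nrow(x) >= 2)
            x[, j] <- zscoreNormalize(x[, j])
    }
    object@exprs <- x
    object
}
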