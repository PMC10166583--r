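# independent oracles shared across test files

# hand-packed FCS builder: writes HEADER, TEXT and DATA bytes directly,
# independent of writeFCS
handBuildFCS <- function(path, kw, dataBytes, version = "FCS3.0",
                         delim = "|") {
    text <- paste0(delim, paste0(names(kw), delim, unname(kw), delim,
                                 collapse = ""))
    textStart <- 58
    textEnd <- textStart + nchar(text) - 1
    dataBeg <- textEnd + 1
    dataEnd <- dataBeg + length(dataBytes) - 1
    f8 <- function(v) formatC(format(v, scientific = FALSE), width = 8)
    header <- paste0(formatC(version, width = -10),
                     f8(textStart), f8(textEnd), f8(dataBeg), f8(dataEnd),
                     f8(0), f8(0))
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(header, con, eos = NULL)
    writeChar(text, con, eos = NULL)
    writeBin(dataBytes, con)
    path
}

int16Kw <- function(tot = 2) c(
    "$DATATYPE" = "I", "$MODE" = "L", "$BYTEORD" = "1,2,3,4",
    "$PAR" = "2", "$TOT" = as.character(tot), "$NEXTDATA" = "0",
    "$BEGINDATA" = "0", "$ENDDATA" = "0",
    "$P1N" = "A", "$P1B" = "16", "$P1R" = "1024", "$P1E" = "0,0",
    "$P2N" = "B", "$P2B" = "16", "$P2R" = "1024", "$P2E" = "0,0")

# naive double-loop oracle for the indicator-correlation marker ranking
oracleMarkerFinder <- function(X, labels, topN) {
    clusters <- sort(unique(labels))
    keep <- apply(X, 2, sd) > 0
    X <- X[, keep, drop = FALSE]
    rmat <- matrix(NA_real_, ncol(X), length(clusters),
                   dimnames = list(colnames(X), clusters))
    for (f in seq_len(ncol(X)))
        for (ci in seq_along(clusters))
            rmat[f, ci] <- cor(X[, f], as.numeric(labels == clusters[ci]))
    out <- NULL
    best <- apply(rmat, 1, function(v) which(v == max(v))[1])
    for (ci in seq_along(clusters)) {
        fs <- which(best == ci)
        if (!length(fs)) next
        fs <- fs[order(rmat[fs, ci], decreasing = TRUE)]
        fs <- head(fs, topN)
        out <- rbind(out, data.frame(feature = colnames(X)[fs],
                                     cluster = clusters[ci],
                                     r = rmat[fs, ci],
                                     rank = seq_along(fs)))
    }
    rownames(out) <- NULL
    out
}

# matrix with nMarkersPer indicator-like features planted per cluster
plantedMatrix <- function(seed = 81, nPerClust = 60, nClust = 4,
                          nMarkersPer = 3, noise = 0.2) {
    set.seed(seed)
    n <- nPerClust * nClust
    labels <- rep(as.character(seq_len(nClust) - 1), each = nPerClust)
    X <- matrix(rnorm(n * 10, sd = noise), n, 10)   # bystander features
    planted <- list()
    for (c in seq_len(nClust)) for (m in seq_len(nMarkersPer)) {
        v <- as.numeric(labels == as.character(c - 1)) +
            rnorm(n, sd = noise)
        X <- cbind(X, v)
        planted[[length(planted) + 1]] <-
            list(feature = sprintf("P%d_%d", c - 1, m),
                 cluster = as.character(c - 1))
    }
    colnames(X) <- c(sprintf("N%02d", 1:10),
                     vapply(planted, `[[`, character(1), "feature"))
    list(X = X, labels = labels, planted = planted)
}
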