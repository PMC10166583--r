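#' Read an FCS 3.0/3.1 file
#'
#' Parses the HEADER, TEXT and DATA segments of a binary FCS file into an
#' [EventMatrix-class]. Supports list-mode data of `$DATATYPE` `F` (32-bit
#' float), `D` (64-bit double) and `I` (unsigned integer, per-channel `$PnB`
#' of 8/16/32 bits), with `$BYTEORD` `1,2,3,4` (little-endian) or `4,3,2,1`
#' (big-endian). Integer data are widened to double. All TEXT keywords are
#' preserved verbatim. Log-amplified channels (`$PnE` with f1 > 0) are left
#' raw; see `delog` and [delogChannels()].
#'
#' Files holding more than one dataset (`$NEXTDATA` != 0) are read for the
#' first dataset only, with a warning.
#'
#' @param path path to the FCS file.
#' @param delog if `TRUE`, channels with a log amplification spec are rescaled
#'   as `f2 * 10^(f1 * x / range)` after reading. Default `FALSE`: modern
#'   float-mode files are already linear.
#' @return An [EventMatrix-class].
#' @seealso [writeFCS()], [harmonizeChannels()]
#' @examples
#' em <- eventMatrix(matrix(runif(30, 0, 1e4), 10, 3,
#'                   dimnames = list(NULL, c("FSC-A", "CD3", "PE"))))
#' f <- tempfile(fileext = ".fcs")
#' writeFCS(em, f)
#' em2 <- readFCS(f)
#' stopifnot(all.equal(exprs(em), exprs(em2), tolerance = 1e-6))
#' @export
readFCS <- function(path, delog = FALSE) {
    if (!file.exists(path)) .stopf("FCS file not found: %s", path)
    raw <- readBin(path, "raw", n = file.size(path))
    if (length(raw) < 58) .stopf("file too short to be FCS: %s", path)

    version <- rawToChar(raw[1:6])
    if (!version %in% c("FCS3.0", "FCS3.1"))
        .stopf("unsupported FCS version/magic '%s' in %s (only FCS3.0/FCS3.1)",
               version, path)

    hdrField <- function(i) {  # 8-byte ASCII offset fields from byte 11
        start <- 11 + (i - 1) * 8
        suppressWarnings(as.numeric(trimws(rawToChar(raw[start:(start + 7)]))))
    }
    textBeg <- hdrField(1); textEnd <- hdrField(2)
    dataBegH <- hdrField(3); dataEndH <- hdrField(4)
    if (is.na(textBeg) || is.na(textEnd) || textBeg < 1 || textEnd <= textBeg)
        .stopf("invalid HEADER TEXT offsets in %s", path)

    # FCS offsets are 0-based byte positions, inclusive
    kw <- parseTextSegment(raw[(textBeg + 1):(textEnd + 1)])
    kwU <- stats::setNames(kw, toupper(names(kw)))
    getKw <- function(name, default = NA_character_) {
        v <- unname(kwU[toupper(name)])
        if (length(v) != 1 || is.na(v)) default else v
    }

    mode <- getKw("$MODE", "L")
    if (toupper(mode) != "L")
        .stopf("unsupported $MODE '%s' in %s: only list mode is supported",
               mode, path)
    dtype <- toupper(getKw("$DATATYPE", ""))
    if (!dtype %in% c("F", "D", "I"))
        .stopf("unsupported $DATATYPE '%s' in %s (supported: F, D, I)",
               dtype, path)
    byteord <- getKw("$BYTEORD", "1,2,3,4")
    endian <- switch(byteord,
        "1,2,3,4" = "little",
        "4,3,2,1" = "big",
        .stopf("unsupported $BYTEORD '%s' in %s", byteord, path))

    par <- as.integer(getKw("$PAR", "0"))
    tot <- as.integer(getKw("$TOT", "0"))
    nextData <- suppressWarnings(as.numeric(getKw("$NEXTDATA", "0")))
    if (!is.na(nextData) && nextData != 0)
        .warnf("%s holds multiple datasets ($NEXTDATA=%d); only the first was read",
               path, as.integer(nextData))

    dataBegT <- suppressWarnings(as.numeric(getKw("$BEGINDATA", "0")))
    dataEndT <- suppressWarnings(as.numeric(getKw("$ENDDATA", "0")))
    # HEADER and TEXT both carry DATA offsets; when both are set they must
    # agree
    if (dataBegH > 0 && dataBegT > 0 && dataBegH != dataBegT)
        .stopf("DATA begin offset mismatch in %s: HEADER says %d, TEXT $BEGINDATA says %d",
               path, dataBegH, dataBegT)
    if (dataEndH > 0 && dataEndT > 0 && dataEndH != dataEndT)
        .stopf("DATA end offset mismatch in %s: HEADER says %d, TEXT $ENDDATA says %d",
               path, dataEndH, dataEndT)
    dataBeg <- if (dataBegT > 0) dataBegT else dataBegH
    dataEnd <- if (dataEndT > 0) dataEndT else dataEndH

    chKw <- function(pfx, default = NA_character_)
        vapply(seq_len(par), function(i) getKw(sprintf("$P%d%s", i, pfx),
                                               default), character(1))
    shortNames <- chKw("N")
    if (anyNA(shortNames) || any(!nzchar(shortNames)))
        .stopf("missing $PnN channel names in %s", path)
    stainNames <- chKw("S")
    ranges <- suppressWarnings(as.numeric(chKw("R", "262144")))
    bits <- suppressWarnings(as.integer(chKw("B", "32")))
    ampl <- lapply(chKw("E", "0,0"), function(e) {
        v <- suppressWarnings(as.numeric(strsplit(e, ",", fixed = TRUE)[[1]]))
        if (length(v) != 2 || anyNA(v)) c(0, 0) else v
    })

    nBytesPerEvent <- switch(dtype,
        F = 4L * par, D = 8L * par, I = sum(bits %/% 8L))
    needed <- as.numeric(nBytesPerEvent) * tot
    if (tot > 0) {
        if (is.na(dataBeg) || dataBeg < 1 || dataEnd < dataBeg)
            .stopf("cannot locate DATA segment in %s", path)
        avail <- dataEnd - dataBeg + 1
        if (avail < needed)
            .stopf("DATA segment of %s holds %d bytes but $TOT=%d x %d channels needs %d",
                   path, as.integer(avail), tot, par, as.integer(needed))
        data <- readDataSegment(raw[(dataBeg + 1):(dataBeg + needed)],
                                dtype, bits, par, tot, endian)
    } else {
        data <- matrix(numeric(0), 0, par)
    }
    colnames(data) <- shortNames

    ch <- DataFrame(short_name = shortNames,
                    stain_name = ifelse(nzchar(stainNames) & !is.na(stainNames),
                                        stainNames, NA_character_),
                    range = ranges,
                    ampl_f1 = vapply(ampl, `[`, numeric(1), 1),
                    ampl_f2 = vapply(ampl, `[`, numeric(1), 2),
                    role = guessRoles(shortNames))
    em <- new("EventMatrix", exprs = data, channels = ch, keywords = kw,
              sourcePath = path)
    if (delog) em <- delogChannels(em)
    em
}

# TEXT segment: first byte is the delimiter; key/value pairs are delimited,
# with a delimiter inside a value escaped by doubling it.
parseTextSegment <- function(rawText) {
    txt <- rawToChar(rawText)
    Encoding(txt) <- "UTF-8"
    delim <- substr(txt, 1, 1)
    body <- substr(txt, 2, nchar(txt))
    tokens <- strsplit(body, delim, fixed = TRUE)[[1]]
    # merge doubled-delimiter escapes: token, "", token  ->  token<delim>token
    merged <- character(0)
    i <- 1L
    while (i <= length(tokens)) {
        cur <- tokens[i]
        while (i + 2L <= length(tokens) && tokens[i + 1L] == "") {
            cur <- paste0(cur, delim, tokens[i + 2L])
            i <- i + 2L
        }
        merged <- c(merged, cur)
        i <- i + 1L
    }
    if (length(merged) %% 2L != 0L)
        stop("malformed TEXT segment: odd number of delimited tokens",
             call. = FALSE)
    keys <- merged[seq(1, length(merged), by = 2)]
    vals <- merged[seq(2, length(merged), by = 2)]
    stats::setNames(vals, trimws(keys))
}

readDataSegment <- function(bytes, dtype, bits, par, tot, endian) {
    n <- par * tot
    if (dtype == "F") {
        v <- readBin(bytes, "double", n = n, size = 4, endian = endian)
    } else if (dtype == "D") {
        v <- readBin(bytes, "double", n = n, size = 8, endian = endian)
    } else {  # I: unsigned integers, possibly mixed widths
        widths <- bits %/% 8L
        if (!all(bits %in% c(8L, 16L, 32L)))
            .stopf("unsupported integer $PnB widths: %s",
                   paste(unique(bits), collapse = ","))
        if (length(unique(widths)) == 1L) {
            w <- widths[1]
            v <- readBin(bytes, "integer", n = n, size = w,
                         signed = (w == 4L), endian = endian)
            if (w == 4L) v <- ifelse(v < 0, v + 4294967296, as.numeric(v))
            v <- as.numeric(v)
        } else {
            # mixed widths: slice per channel
            offsets <- c(0L, cumsum(widths))
            recLen <- offsets[par + 1L]
            starts <- (seq_len(tot) - 1L) * recLen
            m <- matrix(0, tot, par)
            for (j in seq_len(par)) {
                w <- widths[j]
                idx <- as.vector(t(outer(starts + offsets[j],
                                         seq_len(w), `+`)))
                vj <- readBin(bytes[idx], "integer", n = tot, size = w,
                              signed = (w == 4L), endian = endian)
                if (w == 4L) vj <- ifelse(vj < 0, vj + 4294967296,
                                          as.numeric(vj))
                m[, j] <- as.numeric(vj)
            }
            return(m)
        }
    }
    matrix(v, nrow = tot, ncol = par, byrow = TRUE)
}

#' Write an FCS 3.1 file
#'
#' Writes an [EventMatrix-class] as an FCS 3.1 file: list mode, `$DATATYPE=F`
#' (32-bit float), a single TEXT segment with delimiter escaping per the FCS
#' 3.1 standard, and consistent HEADER/TEXT data offsets. Structural keywords
#' are regenerated; all other keywords of the object are carried through
#' verbatim. `readFCS(writeFCS(m))` reproduces the data to 32-bit float
#' precision.
#'
#' @param object an [EventMatrix-class] with finite values.
#' @param path output path.
#' @param byteord `"little"` (FCS 3.1 default, `$BYTEORD=1,2,3,4`) or
#'   `"big"`.
#' @return `path`, invisibly.
#' @export
writeFCS <- function(object, path, byteord = c("little", "big")) {
    stopifnot(is(object, "EventMatrix"))
    byteord <- match.arg(byteord)
    x <- object@exprs
    if (length(x) && any(!is.finite(x)))
        .stopf("cannot write FCS: matrix contains non-finite values")
    par <- ncol(x); tot <- nrow(x)
    ch <- object@channels

    delim <- "/"
    esc <- function(v) gsub(delim, paste0(delim, delim), v, fixed = TRUE)

    structuralPat <- "^\\$(BEGINDATA|ENDDATA|BEGINANALYSIS|ENDANALYSIS|BEGINSTEXT|ENDSTEXT|BYTEORD|DATATYPE|MODE|NEXTDATA|PAR|TOT)$|^\\$P[0-9]+[NSBER]$"
    userKw <- object@keywords
    userKw <- userKw[!grepl(structuralPat, toupper(names(userKw)))]

    kw <- c(
        "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
        "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
        "$BEGINDATA" = "0000000000", "$ENDDATA" = "0000000000",
        "$BYTEORD" = if (byteord == "little") "1,2,3,4" else "4,3,2,1",
        "$DATATYPE" = "F", "$MODE" = "L", "$NEXTDATA" = "0",
        "$PAR" = as.character(par), "$TOT" = as.character(tot))
    for (j in seq_len(par)) {
        kw[sprintf("$P%dN", j)] <- ch$short_name[j]
        if (!is.na(ch$stain_name[j]))
            kw[sprintf("$P%dS", j)] <- ch$stain_name[j]
        kw[sprintf("$P%dB", j)] <- "32"
        kw[sprintf("$P%dE", j)] <- "0,0"
        kw[sprintf("$P%dR", j)] <- format(ch$range[j], scientific = FALSE)
    }
    kw <- c(kw, userKw)

    buildText <- function(kw) {
        paste0(delim,
               paste0(esc(names(kw)), delim, esc(unname(kw)), delim,
                      collapse = ""))
    }
    textStart <- 64L
    textStr <- buildText(kw)
    textLen <- nchar(textStr, type = "bytes")
    nDataBytes <- 4 * par * tot
    if (nDataBytes > 0) {
        dataBeg <- textStart + textLen
        dataEnd <- dataBeg + nDataBytes - 1
    } else {
        dataBeg <- 0; dataEnd <- 0
    }
    kw["$BEGINDATA"] <- sprintf("%010d", dataBeg)
    kw["$ENDDATA"] <- sprintf("%010d", dataEnd)
    textStr <- buildText(kw)
    stopifnot(nchar(textStr, type = "bytes") == textLen)
    textEnd <- textStart + textLen - 1L

    fmt8 <- function(v) {
        s <- if (v <= 99999999) format(v, scientific = FALSE) else "0"
        formatC(s, width = 8, flag = " ")
    }
    header <- paste0("FCS3.1    ",
                     fmt8(textStart), fmt8(textEnd),
                     fmt8(dataBeg), fmt8(dataEnd),
                     fmt8(0), fmt8(0))

    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(header, con, eos = NULL)
    pad <- textStart - nchar(header, type = "bytes")
    if (pad > 0) writeChar(strrep(" ", pad), con, eos = NULL)
    writeChar(textStr, con, eos = NULL)
    if (nDataBytes > 0)
        writeBin(as.vector(t(x)), con, size = 4, endian = byteord)
    invisible(path)
}

#' De-log log-amplified channels
#'
#' Rescales channels stored on a log-amplified integer scale back to linear
#' intensity: `f2 * 10^(f1 * x / range)` for channels whose `$PnE` has
#' `f1 > 0` (with `f2 = 0` treated as 1, per the FCS standard's erratum).
#' Channels with `$PnE = 0,0` are untouched. Off by default in [readFCS()].
#'
#' @param object an [EventMatrix-class].
#' @return The rescaled [EventMatrix-class] (amplification reset to linear).
#' @export
delogChannels <- function(object) {
    ch <- object@channels
    x <- object@exprs
    for (j in seq_len(nrow(ch))) {
        if (ch$ampl_f1[j] > 0) {
            f2 <- if (ch$ampl_f2[j] > 0) ch$ampl_f2[j] else 1
            x[, j] <- f2 * 10^(ch$ampl_f1[j] * x[, j] / ch$range[j])
            ch$ampl_f1[j] <- 0; ch$ampl_f2[j] <- 0
        }
    }
    object@exprs <- x
    object@channels <- ch
    object
}

#' Harmonize backbone channel order across captures
#'
#' Resolves each backbone name in every file and reorders columns so the
#' backbone block comes first, in the requested order, in every file.
#' Resolution order: exact `$PnN` match, then exact `$PnS` (stain name)
#' match, then case-insensitive `$PnN`; fallback matches are logged. Matched
#' channels are renamed to the requested backbone name so downstream
#' predictors align by name; non-backbone channels keep their original
#' relative order. Backbone channels get role `"backbone"`.
#'
#' @param files list of [EventMatrix-class] objects.
#' @param backboneNames character vector of backbone channel names.
#' @return list of harmonized [EventMatrix-class] objects.
#' @export
harmonizeChannels <- function(files, backboneNames) {
    stopifnot(is.list(files), length(backboneNames) >= 1)
    lapply(files, function(em) {
        nm <- em@channels$short_name
        sn <- em@channels$stain_name
        src <- if (nzchar(em@sourcePath)) em@sourcePath else "<in-memory>"
        idx <- vapply(backboneNames, function(b) {
            i <- match(b, nm)
            if (!is.na(i)) return(i)
            i <- match(b, sn)
            if (!is.na(i)) {
                flogMsg(sprintf("channel '%s' matched via stain name in %s",
                                b, src))
                return(i)
            }
            i <- match(tolower(b), tolower(nm))
            if (!is.na(i)) {
                flogMsg(sprintf(
                    "channel '%s' matched case-insensitively ('%s') in %s",
                    b, nm[i], src))
                return(i)
            }
            .stopf("backbone channel '%s' not found in file %s", b, src)
        }, integer(1))
        rest <- setdiff(seq_along(nm), idx)
        em@exprs <- em@exprs[, c(idx, rest), drop = FALSE]
        em@channels <- em@channels[c(idx, rest), ]
        em@channels$short_name[seq_along(backboneNames)] <- backboneNames
        em@channels$role[seq_along(backboneNames)] <- "backbone"
        colnames(em@exprs) <- em@channels$short_name
        validObject(em)
        em
    })
}

#' Assign channel roles from an annotation
#'
#' Marks the annotated exploratory channels of a capture as `"infinity"` (or
#' `"isotype"` for isotype-control captures), leaving backbone/scatter/time
#' roles in place.
#'
#' @param object an [EventMatrix-class].
#' @param infinityChannels channel names carrying exploratory markers.
#' @param isotype logical; `TRUE` when the capture is an isotype control.
#' @return The updated [EventMatrix-class].
#' @export
assignRoles <- function(object, infinityChannels, isotype = FALSE) {
    i <- match(infinityChannels, object@channels$short_name)
    if (anyNA(i))
        .stopf("exploratory channel(s) %s not found in %s",
               paste(infinityChannels[is.na(i)], collapse = ", "),
               if (nzchar(object@sourcePath)) object@sourcePath else "<in-memory>")
    object@channels$role[i] <- if (isotype) "isotype" else "infinity"
    object
}
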