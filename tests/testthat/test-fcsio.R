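test_that("write/read round-trip preserves data, channel order and keywords", {
    em <- makeEventMatrix(n = 1000, seed = 3,
                          chans = sprintf("CH%02d", 1:12))
    f <- tempfile(fileext = ".fcs")
    writeFCS(em, f)
    em2 <- readFCS(f)
    # float32 storage: relative error bounded by float32 epsilon
    expect_lt(max(abs(exprs(em) - exprs(em2)) /
                  pmax(abs(exprs(em)), 1)), 2^-23)
    expect_identical(channelNames(em2), channelNames(em))
    expect_identical(keywords(em2)[["EXPERIMENT"]], "unit-test")
    expect_identical(keywords(em2)[["$CYT"]], "SyntheticWriter")
})

test_that("big- and little-endian encodings of the same data read back identically", {
    em <- makeEventMatrix(n = 64, seed = 5)
    fl <- tempfile(fileext = ".fcs"); fb <- tempfile(fileext = ".fcs")
    writeFCS(em, fl, byteord = "little")
    writeFCS(em, fb, byteord = "big")
    expect_identical(exprs(readFCS(fl)), exprs(readFCS(fb)))
})

test_that("zero-event matrices produce valid, re-readable files", {
    em0 <- eventMatrix(matrix(numeric(0), 0, 2,
                              dimnames = list(NULL, c("A", "B"))))
    f <- tempfile(fileext = ".fcs")
    writeFCS(em0, f)
    back <- readFCS(f)
    expect_identical(nEvents(back), 0L)
    expect_identical(channelNames(back), c("A", "B"))
    expect_identical(keywords(back)[["$TOT"]], "0")
})

test_that("keyword values containing the delimiter are escaped and round-trip verbatim", {
    em <- makeEventMatrix(n = 5)
    em@keywords <- c(em@keywords, "CLONE" = "anti/mouse IgG1",
                     "TRICKY" = "a//b/")
    f <- tempfile(fileext = ".fcs")
    writeFCS(em, f)
    back <- readFCS(f)
    expect_identical(keywords(back)[["CLONE"]], "anti/mouse IgG1")
    expect_identical(keywords(back)[["TRICKY"]], "a//b/")
    # and against a hand-built TEXT segment with a different delimiter
    kw <- c(int16Kw(), "CLONE" = "A||B")   # escaped "|" inside a value
    f2 <- handBuildFCS(tempfile(fileext = ".fcs"), kw,
                       writeBin(c(0L, 1023L, 1023L, 0L), raw(), size = 2,
                                endian = "little"))
    expect_identical(keywords(readFCS(f2))[["CLONE"]], "A|B")
})

test_that("hand-packed 16-bit integer data reads back as the packed values", {
    dataBytes <- writeBin(c(0L, 1023L, 1023L, 0L), raw(), size = 2,
                          endian = "little")
    f <- handBuildFCS(tempfile(fileext = ".fcs"), int16Kw(), dataBytes)
    em <- readFCS(f)
    expect_identical(exprs(em),
                     matrix(c(0, 1023, 1023, 0), 2, 2, byrow = TRUE,
                            dimnames = list(NULL, c("A", "B"))))
    expect_true(is.double(exprs(em)))
})

test_that("hand-packed 64-bit double data reads back exactly", {
    vals <- c(1.25, -3.5, 1e5, 0.1)
    kw <- int16Kw()
    kw["$DATATYPE"] <- "D"; kw["$P1B"] <- "64"; kw["$P2B"] <- "64"
    f <- handBuildFCS(tempfile(fileext = ".fcs"), kw,
                      writeBin(vals, raw(), size = 8, endian = "little"))
    expect_identical(as.vector(t(exprs(readFCS(f)))), vals)
})

test_that("inconsistent $TOT versus DATA byte length is a format error", {
    dataBytes <- writeBin(c(0L, 1023L, 1023L, 0L), raw(), size = 2,
                          endian = "little")
    f <- handBuildFCS(tempfile(fileext = ".fcs"), int16Kw(tot = 5),
                      dataBytes)
    expect_error(readFCS(f), "\\$TOT=5")
})

test_that("unsupported magic, mode and datatype are rejected", {
    f <- tempfile(fileext = ".fcs")
    writeBin(charToRaw(paste0("FCS2.0    ", strrep(" ", 100))), f)
    expect_error(readFCS(f), "FCS2.0")
    kw <- int16Kw(); kw["$MODE"] <- "U"
    f2 <- handBuildFCS(tempfile(fileext = ".fcs"), kw, raw(8))
    expect_error(readFCS(f2), "list mode")
    kw <- int16Kw(); kw["$DATATYPE"] <- "A"
    f3 <- handBuildFCS(tempfile(fileext = ".fcs"), kw, raw(8))
    expect_error(readFCS(f3), "DATATYPE")
})

test_that("HEADER and TEXT disagreeing on DATA offsets errors naming both values", {
    kw <- int16Kw()
    kw["$BEGINDATA"] <- "999"   # conflicts with the header offset
    f <- handBuildFCS(tempfile(fileext = ".fcs"), kw,
                      writeBin(c(0L, 1L, 2L, 3L), raw(), size = 2,
                               endian = "little"))
    expect_error(readFCS(f), "HEADER.*TEXT|999")
})

test_that("multi-dataset files read the first dataset with a warning", {
    kw <- int16Kw(); kw["$NEXTDATA"] <- "4242"
    f <- handBuildFCS(tempfile(fileext = ".fcs"), kw,
                      writeBin(c(0L, 1L, 2L, 3L), raw(), size = 2,
                               endian = "little"))
    expect_warning(em <- readFCS(f), "NEXTDATA")
    expect_identical(nEvents(em), 2L)
})

test_that("non-finite values are refused at write time", {
    em <- makeEventMatrix(n = 5)
    x <- exprs(em); x[1, 1] <- NaN
    em@exprs <- x
    expect_error(writeFCS(em, tempfile()), "non-finite")
})

test_that("harmonizeChannels aligns backbone order across permuted panels", {
    m <- matrix(as.numeric(seq_len(20)), 5, 4)
    emA <- eventMatrix(m, channelNames = c("CD3", "CD4", "PE", "Time"))
    emB <- eventMatrix(m[, c(2, 3, 1, 4)],
                       channelNames = c("CD4", "PE", "CD3", "Time"))
    h <- harmonizeChannels(list(emA, emB), c("CD3", "CD4"))
    expect_identical(channelNames(h[[1]])[1:2], c("CD3", "CD4"))
    expect_identical(channelNames(h[[2]])[1:2], c("CD3", "CD4"))
    # values follow their channels through the permutation
    expect_identical(exprs(h[[2]])[, "CD3"], m[, 1])
    expect_identical(unname(channelRoles(h[[1]])[1:2]),
                     c("backbone", "backbone"))
})

test_that("backbone names fall back to stain names ($PnS) with a log message", {
    em <- eventMatrix(matrix(1:10, 5, 2),
                      channelNames = c("FL1-A", "FL2-A"),
                      stainNames = c("CD8", "CD19"))
    expect_message(h <- harmonizeChannels(list(em), c("CD8", "CD19")),
                   "stain name")
    expect_identical(channelNames(h[[1]]), c("CD8", "CD19"))
})

test_that("a backbone channel missing from one file errors naming that file", {
    emA <- eventMatrix(matrix(1:10, 5, 2), channelNames = c("CD3", "CD4"))
    emB <- eventMatrix(matrix(1:10, 5, 2), channelNames = c("CD3", "CD8"))
    emB@sourcePath <- "fileB.fcs"
    expect_error(harmonizeChannels(list(emA, emB), c("CD3", "CD4")),
                 "CD4.*fileB")
})

test_that("log-amplified channels de-log on request only", {
    kw <- int16Kw()
    kw["$P1E"] <- "4,1"   # 4 decades over the 1024 range
    f <- handBuildFCS(tempfile(fileext = ".fcs"), kw,
                      writeBin(c(512L, 100L, 256L, 200L), raw(), size = 2,
                               endian = "little"))
    raw <- readFCS(f)
    expect_identical(unname(exprs(raw)[1, "A"]), 512)
    lin <- readFCS(f, delog = TRUE)
    expect_equal(unname(exprs(lin)[1, "A"]), 1 * 10^(4 * 512 / 1024))
    expect_identical(exprs(lin)[, "B"], exprs(raw)[, "B"])  # linear untouched
})
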