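makeTransformedFiles <- function(nFiles = 3, n = 900, seed = 61) {
    set.seed(seed)
    files <- lapply(seq_len(nFiles), function(i) {
        X <- matrix(rnorm(n * 4, 2), n, 4,
                    dimnames = list(NULL, c("B1", "B2", "PE", "Time")))
        eventMatrix(X, roles = c("backbone", "backbone", "infinity", "time"))
    })
    names(files) <- paste0("f", seq_len(nFiles))
    splits <- lapply(files, function(em) splitEvents(nEvents(em), 0.5,
                                                     seed = 7))
    list(files = files, splits = splits)
}

test_that("pooling draws the exact per-file validation counts, in file order", {
    fx <- makeTransformedFiles()
    pool <- poolEvents(fx$files, fx$splits, nPerFile = 300, seed = 5,
                       backboneNames = c("B1", "B2"))
    expect_identical(nrow(pool$backbone), 900L)
    expect_identical(as.vector(table(pool$eventMeta$source_file)[
        paste0("f", 1:3)]), rep(300L, 3))
    expect_identical(unique(pool$eventMeta$source_file), paste0("f", 1:3))
    # only validation events are pooled, with traceable provenance
    for (f in names(fx$files)) {
        idx <- pool$eventMeta$original_event_index[
            pool$eventMeta$source_file == f]
        expect_true(all(idx %in% fx$splits[[f]]@valIdx))
        expect_identical(pool$backbone[pool$eventMeta$source_file == f, ],
                         exprs(fx$files[[f]])[idx, c("B1", "B2")])
    }
    # determinism
    pool2 <- poolEvents(fx$files, fx$splits, nPerFile = 300, seed = 5,
                        backboneNames = c("B1", "B2"))
    expect_identical(pool$backbone, pool2$backbone)
    expect_identical(pool$eventMeta, pool2$eventMeta)
})

test_that("files short of validation events contribute all of them with a warning", {
    fx <- makeTransformedFiles(nFiles = 2, n = 200)
    expect_warning(                       # one warning per short file
        expect_warning(pool <- poolEvents(fx$files, fx$splits,
                                          nPerFile = 500, seed = 1,
                                          backboneNames = c("B1", "B2")),
                       "only 100 validation"),
        "only 100 validation")
    expect_identical(as.vector(table(pool$eventMeta$source_file)),
                     rep(100L, 2))
})

test_that("reference mode takes every event and carries extra channels as passthrough", {
    ref <- eventMatrix(matrix(rnorm(500 * 4, 2), 500, 4,
                              dimnames = list(NULL,
                                              c("B1", "B2", "CD99", "Time"))),
                       roles = c("backbone", "backbone", "passthrough",
                                 "time"))
    sub <- useReference(ref, c("B1", "B2"))
    expect_identical(nrow(sub$backbone), 500L)
    expect_identical(colnames(sub$passthrough), c("CD99", "Time"))
    expect_identical(sub$eventMeta$original_event_index, 1:500)
    expect_error(useReference(ref, c("B1", "B9")), "B9")
})

test_that("assembled experiments keep the backbone/imputed/passthrough block order", {
    fx <- makeTransformedFiles()
    pool <- poolEvents(fx$files, fx$splits, nPerFile = 100, seed = 2,
                       backboneNames = c("B1", "B2"))
    imp <- matrix(rnorm(300 * 2), 300, 2,
                  dimnames = list(NULL, c("M1", "M2")))
    ie <- buildImputedExperiment(pool, imp, runMeta = list(seed = 2))
    rd <- SummarizedExperiment::rowData(ie)
    expect_identical(as.character(rd$role),
                     c("backbone_transformed", "backbone_transformed",
                       "imputed", "imputed", "passthrough"))
    expect_identical(rownames(ie), c("B1", "B2", "M1", "M2", "Time"))
    expect_true(validObject(ie))
    # events traceable
    cd <- SummarizedExperiment::colData(ie)
    expect_true(all(c("source_file", "original_event_index") %in%
                    colnames(cd)))
})

test_that("h5ad and feather exports round-trip the matrix exactly", {
    fx <- makeTransformedFiles(nFiles = 2, n = 300)
    pool <- poolEvents(fx$files, fx$splits, nPerFile = 80, seed = 3,
                       backboneNames = c("B1", "B2"))
    imp <- matrix(rnorm(160), 160, 1, dimnames = list(NULL, "M1"))
    ie <- buildImputedExperiment(pool, imp,
                                 runMeta = list(seed = 3, mode = "pool"))
    for (fmt in c("h5ad", "feather")) {
        f <- tempfile(fileext = paste0(".", fmt))
        exportAnnotated(ie, f, fmt)
        back <- importAnnotated(f, fmt)
        expect_identical(SummarizedExperiment::assay(back, "exprs"),
                         SummarizedExperiment::assay(ie, "exprs"))
        expect_identical(
            SummarizedExperiment::colData(back)$source_file,
            as.character(SummarizedExperiment::colData(ie)$source_file))
    }
    # h5ad also restores roles and run metadata
    f <- tempfile(fileext = ".h5ad")
    exportAnnotated(ie, f, "h5ad")
    back <- importAnnotated(f, "h5ad")
    expect_identical(SummarizedExperiment::rowData(back)$role,
                     as.character(SummarizedExperiment::rowData(ie)$role))
    expect_identical(S4Vectors::metadata(back)$mode, "pool")
    expect_error(exportAnnotated(ie, tempfile(), "parquet"))
})

test_that("csv export of a 5x3 toy matrix matches the hand-written golden file", {
    X <- matrix(c(1, 2, 3,
                  4, 5, 6,
                  7, 8, 9,
                  10, 11, 12,
                  13, 14, 15.5), 5, 3, byrow = TRUE,
                dimnames = list(NULL, c("B1", "M1", "Extra")))
    sub <- list(backbone = X[, 1, drop = FALSE],
                passthrough = X[, 3, drop = FALSE],
                eventMeta = data.frame(
                    source_file = rep("toy", 5),
                    original_event_index = c(2L, 4L, 6L, 8L, 10L)))
    ie <- buildImputedExperiment(sub, X[, 2, drop = FALSE])
    f <- tempfile(fileext = ".csv")
    exportAnnotated(ie, f, "csv")
    golden <- c(
        "\"meta_source_file\",\"meta_original_event_index\",\"B1\",\"M1\",\"Extra\"",
        "\"toy\",2,1,2,3",
        "\"toy\",4,4,5,6",
        "\"toy\",6,7,8,9",
        "\"toy\",8,10,11,12",
        "\"toy\",10,13,14,15.5")
    expect_identical(readLines(f), golden)
    back <- importAnnotated(f, "csv")
    expect_equal(t(SummarizedExperiment::assay(back, "exprs")),
                 X, ignore_attr = TRUE)
})
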