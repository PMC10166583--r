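tinySpec <- function(noiseSd = 0.04, seed = 91, n = 1500,
                     scale = "transformed", weights = c(0.6, 0.4)) {
    means <- matrix(c(0.3, 0.4, 0.5,
                      0.6, 0.7, 0.4), 2, 3, byrow = TRUE,
                    dimnames = list(NULL, c("B1", "B2", "B3")))
    syntheticPanelSpec(means, populationWeights = weights,
                       backboneCov = diag(0.05^2, 3),
                       markers = list(list(name = "M1",
                                           link = linkLinear("B1", 1),
                                           noiseSd = noiseSd)),
                       nEventsPerFile = n, seed = seed, scale = scale)
}

test_that("a noiseless marker equals its link function exactly", {
    g <- generatePanel(tinySpec(noiseSd = 0), file.path(tempdir(), "noiseless"))
    em <- readFCS(g$files[["M1"]])
    truth <- read.delim(g$truth[["M1"]])
    expect_equal(exprs(em)[, "PE"], truth$true_M1, tolerance = 1e-7,
                 ignore_attr = TRUE)
    expect_equal(exprs(em)[, "PE"], exprs(em)[, "B1"], tolerance = 1e-7,
                 ignore_attr = TRUE)
})

test_that("generation is byte-identical for a fixed seed", {
    d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
    g1 <- generatePanel(tinySpec(), d1)
    g2 <- generatePanel(tinySpec(), d2)
    expect_identical(readBin(g1$files[["M1"]], "raw",
                             file.size(g1$files[["M1"]])),
                     readBin(g2$files[["M1"]], "raw",
                             file.size(g2$files[["M1"]])))
    # and a different seed changes the bytes
    g3 <- generatePanel(tinySpec(seed = 92), file.path(tempdir(), "det3"))
    expect_false(identical(
        readBin(g1$files[["M1"]], "raw", file.size(g1$files[["M1"]])),
        readBin(g3$files[["M1"]], "raw", file.size(g3$files[["M1"]]))))
})

test_that("population frequencies match the spec weights at large n", {
    g <- generatePanel(tinySpec(n = 100000, weights = c(0.7, 0.3)),
                       file.path(tempdir(), "lln"))
    truth <- read.delim(g$truth[["M1"]])
    freq <- as.vector(table(truth$population)) / nrow(truth)
    expect_lt(max(abs(freq - c(0.7, 0.3))), 0.01)
})

test_that("raw-scale panels invert the fixed logicle back to display values", {
    # same seed, two scales: logicle of the raw-scale file must recover the
    # display-scale file (up to float32 storage)
    gRaw <- generatePanel(tinySpec(scale = "raw"),
                          file.path(tempdir(), "rawscale"))
    gDisp <- generatePanel(tinySpec(scale = "transformed"),
                           file.path(tempdir(), "dispscale"))
    lp <- logicleParams(262144, 0.5, 4.5, 0)
    raw <- exprs(readFCS(gRaw$files[["M1"]]))
    disp <- exprs(readFCS(gDisp$files[["M1"]]))
    for (ch in c("B1", "B2", "B3", "PE"))
        expect_equal(logicle(raw[, ch], lp), disp[, ch], tolerance = 1e-4)
})

test_that("attainable correlation follows sd(link)/sqrt(sd(link)^2 + noise^2)", {
    # single population, identity link on one channel: sd(link) = 0.05
    means <- matrix(0.5, 1, 2, dimnames = list(NULL, c("B1", "B2")))
    mkSpec <- function(noiseSd) syntheticPanelSpec(
        means, backboneCov = diag(0.05^2, 2),
        markers = list(list(name = "M", link = linkLinear("B1", 1),
                            noiseSd = noiseSd)),
        nEventsPerFile = 100, seed = 5, scale = "transformed")
    expect_equal(attainableR(mkSpec(0), "M"), 1)
    expect_equal(attainableR(mkSpec(0.05), "M", nMC = 200000), 1 / sqrt(2),
                 tolerance = 0.005)
    rs <- vapply(c(0, 0.02, 0.05, 0.1, 0.3), function(s)
        attainableR(mkSpec(s), "M", nMC = 20000), numeric(1))
    expect_true(all(diff(rs) < 0))   # monotone decreasing in noise
    expect_error(attainableR(mkSpec(0), "nope"), "no marker")
})

test_that("panel annotation links files, channels, markers and isotype groups", {
    px <- smallPanel()
    ann <- px$gen$annotation
    expect_setequal(ann$marker_name[!ann$isotype_control],
                    c("Marker01", "Marker02", "Marker03"))
    expect_identical(sum(ann$isotype_control), 1L)
    expect_identical(unique(ann$infinity_channel), "PE")
    expect_true(all(file.exists(px$gen$files)))
    expect_true(file.exists(px$gen$referencePath))
    # multi-channel capture support: two markers in one file
    means <- matrix(c(0.4, 0.6), 1, 2, dimnames = list(NULL, c("B1", "B2")))
    spec <- syntheticPanelSpec(
        means, backboneCov = diag(0.04^2, 2),
        markers = list(
            list(name = "Mpe", link = linkLinear("B1", 1), noiseSd = 0.02,
                 file = "combo", channel = "PE"),
            list(name = "Mapc", link = linkLinear("B2", 1), noiseSd = 0.02,
                 file = "combo", channel = "APC")),
        nEventsPerFile = 300, seed = 2, scale = "transformed")
    g <- generatePanel(spec, file.path(tempdir(), "combo"))
    expect_length(g$files, 1)
    em <- readFCS(g$files[["combo"]])
    expect_true(all(c("PE", "APC") %in% channelNames(em)))
})

test_that("infeasible covariance is rejected", {
    means <- matrix(0.5, 1, 2, dimnames = list(NULL, c("B1", "B2")))
    badCov <- matrix(c(1, 2, 2, 1), 2, 2)   # not positive semi-definite
    expect_error(syntheticPanelSpec(means, backboneCov = badCov,
                                    nEventsPerFile = 10),
                 "positive semi-definite")
})
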