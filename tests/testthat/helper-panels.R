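# shared fixtures, generated in code at test time

# small in-memory EventMatrix with distinctive keywords
makeEventMatrix <- function(n = 50, seed = 1,
                            chans = c("FSC-A", "CD3", "CD4", "PE", "Time")) {
    set.seed(seed)
    m <- matrix(runif(n * length(chans), 0, 1e4), n, length(chans),
                dimnames = list(NULL, chans))
    if ("Time" %in% chans) m[, "Time"] <- seq_len(n)
    eventMatrix(m, keywords = c("$CYT" = "SyntheticWriter",
                                "EXPERIMENT" = "unit-test"))
}

# one generated panel per configuration, cached across tests in a session
panelCache <- new.env(parent = emptyenv())

cachedPanel <- function(key, specFun) {
    if (is.null(panelCache[[key]])) {
        spec <- specFun()
        dir <- file.path(tempdir(), paste0("flowImpute-", key))
        panelCache[[key]] <- list(spec = spec,
                                  gen = generatePanel(spec, dir,
                                                      reference = TRUE))
    }
    panelCache[[key]]
}

smallPanel <- function() {
    cachedPanel("small", function()
        examplePanelSpec(nMarkers = 3, nBackbone = 7,
                         nEventsPerFile = 3000, seed = 17,
                         isotypeBetas = c(0, 0.5, 0.8)))
}

fastBoost <- function(nrounds = 60) boostParams(nrounds = nrounds)
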