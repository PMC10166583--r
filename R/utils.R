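# internal helpers

# Deterministic 31-bit polynomial string hash, so per-model seeds depend
# only on (run seed, file, marker) and adding a file never perturbs the
# seeds of other models. Doubles hold intermediate products exactly
# (< 2^53).
deriveSeed <- function(runSeed, ...) {
    parts <- paste(c(as.character(runSeed), vapply(list(...), as.character,
                                                   character(1))),
                   collapse = "\x1f")
    h <- 0
    for (b in utf8ToInt(parts))
        h <- (h * 131 + b) %% 2147483629
    as.integer(h)
}

flogMsg <- function(...) {
    message("[flowImpute] ", ...)
}

# round-half-up, documented convention for split sizes
roundHalfUp <- function(x) floor(x + 0.5)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
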