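#' Isotype background correction
#'
#' Removes nonspecific antibody binding from imputed marker columns using
#' imputed isotype-control columns. For each assigned marker `m` with
#' isotype column `iso`, an ordinary least squares fit
#' `m = alpha + beta * iso` is computed across the pooled events and the
#' corrected value is `m - beta_hat * iso`. The intercept is retained, so the
#' marker keeps its location; only the component tracking the isotype is
#' removed. The slope is clamped at `>= 0`: an isotype control can only add
#' background, never remove it (a negative fit is reported and skipped with a
#' warning). Markers without an assignment pass through untouched, bitwise.
#' Correction operates on the regression (transformed) scale, where the
#' imputation itself lives.
#'
#' @param imputed numeric matrix, events x markers (must include the isotype
#'   columns).
#' @param assignments data.frame with columns `marker_name` and
#'   `isotype_marker_name` (one row per marker to correct).
#' @return The corrected matrix, with a `"fitReport"` attribute: a
#'   data.frame of `marker`, `isotype`, `alpha`, `beta` (clamped),
#'   `beta_raw`, `r_squared` per corrected marker.
#' @examples
#' set.seed(1)
#' iso <- rexp(500); true <- rnorm(500, 2)
#' X <- cbind(CD99 = true + 0.8 * iso, IgG1 = iso)
#' out <- correctBackground(X, data.frame(marker_name = "CD99",
#'                                        isotype_marker_name = "IgG1"))
#' attr(out, "fitReport")$beta  # ~0.8
#' @export
correctBackground <- function(imputed, assignments) {
    stopifnot(is.matrix(imputed),
              all(c("marker_name", "isotype_marker_name") %in%
                  colnames(assignments)))
    if (nrow(imputed) < 10)
        .stopf("background correction needs at least 10 events (got %d)",
               nrow(imputed))
    report <- list()
    out <- imputed
    for (i in seq_len(nrow(assignments))) {
        mk <- as.character(assignments$marker_name[i])
        iso <- as.character(assignments$isotype_marker_name[i])
        for (col in c(mk, iso))
            if (!col %in% colnames(imputed))
                .stopf("background correction: column '%s' not found", col)
        x <- imputed[, iso]
        y <- imputed[, mk]
        if (stats::sd(x) == 0) {
            .warnf("isotype column '%s' has zero variance; '%s' left uncorrected",
                   iso, mk)
            report[[i]] <- data.frame(marker = mk, isotype = iso,
                                      alpha = NA_real_, beta = 0,
                                      beta_raw = NA_real_,
                                      r_squared = NA_real_)
            next
        }
        fit <- stats::lm.fit(cbind(1, x), y)
        alpha <- fit$coefficients[1]
        betaRaw <- fit$coefficients[2]
        beta <- betaRaw
        if (betaRaw < 0) {
            .warnf("marker '%s' anticorrelated with isotype '%s' (beta=%.3g); slope clamped to 0",
                   mk, iso, betaRaw)
            beta <- 0
        }
        r2 <- if (stats::sd(y) > 0) stats::cor(x, y)^2 else NA_real_
        out[, mk] <- y - beta * x
        report[[i]] <- data.frame(marker = mk, isotype = iso,
                                  alpha = unname(alpha), beta = unname(beta),
                                  beta_raw = unname(betaRaw), r_squared = r2)
    }
    attr(out, "fitReport") <- do.call(rbind, report)
    out
}

#' Build isotype assignments from an annotation table
#'
#' The annotation's `isotype_group` column links each marker to an isotype
#' class; the marker flagged `isotype_control = TRUE` within a group is used
#' as that group's isotype column. Markers without a group (or in a group
#' with no control) are left unassigned.
#'
#' @param annotation data.frame with `marker_name`, optional `isotype_group`
#'   and optional logical `isotype_control` columns.
#' @return data.frame of `marker_name`, `isotype_marker_name` (possibly
#'   0-row).
#' @export
isotypeAssignments <- function(annotation) {
    empty <- data.frame(marker_name = character(),
                        isotype_marker_name = character())
    if (!"isotype_group" %in% colnames(annotation)) return(empty)
    ctrl <- if ("isotype_control" %in% colnames(annotation))
        as.logical(annotation$isotype_control) else
        rep(FALSE, nrow(annotation))
    ctrl[is.na(ctrl)] <- FALSE
    grp <- as.character(annotation$isotype_group)
    out <- list()
    for (g in unique(grp[!is.na(grp) & nzchar(grp)])) {
        inG <- which(grp == g & !is.na(grp))
        isoRow <- inG[ctrl[inG]]
        if (length(isoRow) == 0) {
            .warnf("isotype group '%s' has no control capture; markers left uncorrected", g)
            next
        }
        if (length(isoRow) > 1)
            .warnf("isotype group '%s' has several controls; using '%s'",
                   g, annotation$marker_name[isoRow[1]])
        isoName <- as.character(annotation$marker_name[isoRow[1]])
        targets <- setdiff(inG, isoRow[1])
        if (length(targets))
            out[[g]] <- data.frame(
                marker_name = as.character(annotation$marker_name[targets]),
                isotype_marker_name = isoName)
    }
    if (length(out)) do.call(rbind, c(out, make.row.names = FALSE)) else empty
}
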