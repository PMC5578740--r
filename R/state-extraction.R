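#' Build the brain-state mask
#'
#' Voxels enter the state mask when their gray-matter probability and the
#' group-average deconvolution R-squared both reach their thresholds
#' (defaults 0.5 and 0.27). The result is the mask all brain-state
#' patterns, nuisance templates and projections are restricted to.
#'
#' @param grayProb per-voxel gray-matter probability
#'   (\linkS4class{MaskedVolume} or numeric).
#' @param groupR2 per-voxel group-average model R-squared.
#' @param pThresh gray-matter probability threshold.
#' @param r2Thresh R-squared threshold.
#' @return logical per-voxel inclusion vector with attributes recording
#'   the thresholds.
#' @export
buildStateMask <- function(grayProb, groupR2, pThresh = 0.5,
                           r2Thresh = 0.27) {
    if (is(grayProb, "MaskedVolume")) grayProb <- grayProb@values
    if (is(groupR2, "MaskedVolume")) groupR2 <- groupR2@values
    stopifnot(length(grayProb) == length(groupR2))
    keep <- grayProb >= pThresh & groupR2 >= r2Thresh
    if (!any(keep)) stop("state mask is empty at these thresholds")
    structure(keep, pThresh = pThresh, r2Thresh = r2Thresh)
}

#' Covariate-adjusted group-average trial time courses
#'
#' Combines the scaled per-session trial averages of one condition cell
#' into an idealized group time course: each voxel x lag value is
#' regressed across sessions on mean-centered age, total displacement and
#' the incorrect-trial proportion, and the prediction is taken at mean
#' age, zero displacement and perfect performance (the intercept). With no
#' covariates this reduces to the plain group mean.
#'
#' @param cellAverages list of voxels x lags matrices, one per session,
#'   all for the same condition cell.
#' @param covariates data.frame with one row per session and numeric
#'   columns age, displacement, incorrectProp (optional; any subset).
#' @return voxels x lags idealized average matrix.
#' @export
idealizedTimecourse <- function(cellAverages, covariates = NULL) {
    stopifnot(length(cellAverages) >= 1)
    dims <- dim(cellAverages[[1]])
    Y <- t(vapply(cellAverages, as.numeric, numeric(prod(dims))))
    X <- cbind(intercept = rep(1, nrow(Y)))
    if (!is.null(covariates))
        for (v in intersect(c("age", "displacement", "incorrectProp"),
                            names(covariates))) {
            x <- covariates[[v]]
            ## age and displacement are centered (predictions at their
            ## means); the incorrect-trial proportion is left raw so the
            ## intercept is the perfect-performance prediction
            if (v %in% c("age", "displacement")) x <- x - mean(x)
            X <- cbind(X, setNames(list(x), v)[[1]])
            colnames(X)[ncol(X)] <- v
        }
    ## covariate adjustment needs spare degrees of freedom; otherwise
    ## fall back to the plain group mean
    if (ncol(X) == 1 || nrow(Y) < ncol(X) + 2 ||
        qr(X)$rank < ncol(X)) {
        out <- colMeans(Y)
    } else {
        B <- olsCoef(X, Y)
        out <- B[1, ]     # prediction at centered-age 0, zero covariates
    }
    matrix(out, dims[1], dims[2])
}

#' Extract epoch patterns from trial-average time courses
#'
#' Pulls single volumes out of the long-delay idealized trial averages at
#' the TR of a task event plus a hemodynamic lag: the encoding saccade or
#' the MGS at +\code{lagTr} (4 TRs = 6 s, where the BOLD response peaks),
#' or the TR immediately before the MGS for the maintenance epoch
#' (\code{event = "pre-mgs"}).
#'
#' @param cellMatrices named list of voxels x lags matrices for the
#'   long-delay condition cells (lag 0 is the encoding-saccade TR).
#' @param durTr named integer vector: trial duration in TRs (encoding
#'   saccade to MGS) per cell.
#' @param event one of "encode", "mgs", "pre-mgs".
#' @param lagTr hemodynamic lag in TRs for encode/mgs events.
#' @return voxels x cells matrix of extracted patterns (columns named by
#'   cell).
#' @export
extractEpochPattern <- function(cellMatrices, durTr,
                                event = c("encode", "mgs", "pre-mgs"),
                                lagTr = 4L) {
    event <- match.arg(event)
    out <- NULL
    for (lab in names(cellMatrices)) {
        lag0 <- switch(event,
                       encode = lagTr,
                       mgs = durTr[[lab]] + lagTr,
                       `pre-mgs` = durTr[[lab]] - 1L)
        if (lag0 < 0 || lag0 >= ncol(cellMatrices[[lab]]))
            stop("requested lag ", lag0, " outside the FIR window for ",
                 lab)
        out <- cbind(out, cellMatrices[[lab]][, lag0 + 1L])
    }
    colnames(out) <- names(cellMatrices)
    out
}

#' Residualize target volumes on reference volumes
#'
#' Replaces each target pattern by its residual from an across-voxel OLS
#' fit on the reference patterns (intercept included), the
#' orthogonalization step that removes earlier task activity from the
#' maintenance and retrieval patterns.
#'
#' @param targets voxels x k matrix (or vector) of patterns to clean.
#' @param references voxels x m matrix of patterns to remove; must be
#'   linearly independent.
#' @return matrix of residualized targets, same shape as \code{targets}.
#' @export
orthogonalizeVolumes <- function(targets, references) {
    targets <- as.matrix(targets)
    X <- cbind(intercept = 1, as.matrix(references))
    qrX <- qr(X, tol = 1e-10)
    if (qrX$rank < ncol(X))
        stop("collinear reference patterns")
    targets - X %*% qr.coef(qrX, targets)
}

#' Mean/spatial decomposition of per-hemifield patterns
#'
#' The mean component is the hemifield average (right + left)/2, averaged
#' across contributing conditions; the spatial component is the
#' right-minus-left difference. The decomposition is exactly invertible:
#' mean + spatial/2 reconstructs the right pattern and mean - spatial/2
#' the left.
#'
#' @param right,left voxels x conditions matrices (or vectors) of
#'   per-hemifield patterns.
#' @return list with \code{mean} and \code{spatial} per-voxel vectors.
#' @export
meanSpatialDecompose <- function(right, left) {
    right <- as.matrix(right); left <- as.matrix(left)
    if (!all(dim(right) == dim(left)))
        stop("right and left patterns must have matching dimensions")
    list(mean = rowMeans((right + left) / 2),
         spatial = rowMeans(right - left))
}

#' Mirror symmetrization of a brain-state set
#'
#' Averages each mean component with its mirrored copy and each spatial
#' component with the sign-inverted mirrored copy, so the outputs are
#' exactly symmetric (mean) or antisymmetric (spatial) under the mask's
#' left/right pairing. This removes asymmetric noise accumulated by the
#' regression-based orthogonalization.
#'
#' @param states a \linkS4class{BrainStateSet}.
#' @return a \linkS4class{BrainStateSet} with symmetrized patterns
#'   (re-normalized to unit norm).
#' @export
mirrorSymmetrize <- function(states) {
    stopifnot(is(states, "BrainStateSet"))
    mask <- states@mask
    p <- states@patterns
    out <- p
    for (j in seq_len(ncol(p))) {
        m <- mirrorValues(p[, j], mask)
        out[, j] <- if (grepl("_mean$", colnames(p)[j]))
            (p[, j] + m) / 2 else (p[, j] - m) / 2
        if (sqrt(sum(out[, j]^2)) > 0)
            out[, j] <- centerUnitNorm(out[, j])
    }
    initialize(states, patterns = out,
               provenance = paste(states@provenance, "+ mirror"))
}

#' Estimate the canonical brain states from session trial averages
#'
#' The full state-construction recipe: idealized (covariate-adjusted)
#' group averages of the long-delay trial cells; VME patterns at the
#' encoding saccade + lag; maintenance patterns at the TR before the MGS,
#' residualized on the encoding-saccade volumes and the VME patterns;
#' retrieval patterns at the MGS + lag, residualized on every pre-MGS
#' volume; mean/spatial decomposition per state; mirror symmetrization;
#' centering and unit-norm scaling.
#'
#' @param sessionFits list of \code{\link{firDeconvolve}} results (one
#'   per session).
#' @param covariates optional data.frame (one row per session) with age,
#'   displacement, incorrectProp for the idealized averages.
#' @param mask the \linkS4class{BrainMask} of the sessions.
#' @param lagTr hemodynamic lag in TRs (4 = 6 s).
#' @param includeEncodeRefs also residualize the maintenance patterns
#'   on the encoding-saccade-TR volumes. Off by default: when no task
#'   activity precedes the encoding saccade those volumes carry only
#'   estimation noise, whose spatial correlation with the later-lag
#'   estimates strips real maintenance signal; turn on for data with
#'   appreciable pre-saccade stimulus activity.
#' @return a \linkS4class{BrainStateSet}.
#' @export
estimateBrainStates <- function(sessionFits, covariates = NULL, mask,
                                lagTr = 4L, includeEncodeRefs = FALSE) {
    cells <- sessionFits[[1]]$cells
    longLabs <- cells$label[cells$delay_s == max(cells$delay_s)]
    durTr <- setNames(cells$durTr, cells$label)[longLabs]
    hemis <- setNames(cells$hemifield, cells$label)[longLabs]
    ideal <- list()
    for (lab in longLabs)
        ideal[[lab]] <- idealizedTimecourse(
            lapply(sessionFits, function(f) f$averages[[lab]]),
            covariates)

    vme <- extractEpochPattern(ideal, durTr, "encode", lagTr)
    maint <- extractEpochPattern(ideal, durTr, "pre-mgs", lagTr)
    retr <- extractEpochPattern(ideal, durTr, "mgs", lagTr)

    ## references: encoding-saccade volumes and VME patterns for the
    ## maintenance states; every pre-MGS volume for the retrieval states.
    ## Each reference set is closed under the mirror pairing so the final
    ## symmetrization step cannot reintroduce reference components, and
    ## rank-pruned so the references stay independent.
    mirrorClose <- function(refs) {
        refs <- cbind(refs, refs[mask@pairing, , drop = FALSE])
        qrR <- qr(cbind(1, refs), tol = 1e-10)
        keep <- setdiff(qrR$pivot[seq_len(qrR$rank)], 1L) - 1L
        refs[, keep, drop = FALSE]
    }
    maintRefs <- if (includeEncodeRefs)
        cbind(vapply(longLabs, function(l) ideal[[l]][, 1],
                     numeric(nrow(vme))), vme) else vme
    maint <- orthogonalizeVolumes(maint, mirrorClose(maintRefs))
    preMgs <- do.call(cbind, lapply(longLabs, function(l)
        ideal[[l]][, seq_len(durTr[[l]]), drop = FALSE]))
    retr <- orthogonalizeVolumes(retr, mirrorClose(preMgs))

    decomp <- function(mat) {
        r <- mat[, hemis[colnames(mat)] > 0, drop = FALSE]
        l <- mat[, hemis[colnames(mat)] < 0, drop = FALSE]
        meanSpatialDecompose(r, l)
    }
    dv <- decomp(vme); dm <- decomp(maint); dr <- decomp(retr)
    pats <- cbind(vme_mean = dv$mean, vme_spatial = dv$spatial,
                  maint_mean = dm$mean, maint_spatial = dm$spatial,
                  retr_mean = dr$mean, retr_spatial = dr$spatial)
    pats <- apply(pats, 2, centerUnitNorm)
    colnames(pats) <- .stateLabels
    states <- new("BrainStateSet", patterns = pats, mask = mask,
                  lagTr = as.integer(lagTr),
                  provenance = sprintf(
                      "estimated from %d session(s), long-delay trials",
                      length(sessionFits)))
    mirrorSymmetrize(states)
}
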