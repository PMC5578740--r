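#' Legendre polynomial drift regressors
#'
#' Legendre polynomials P0..Porder evaluated on an equally spaced grid over
#' [-1, 1] spanning the run, the standard slow-drift basis for task fMRI
#' regression.
#'
#' @param nTr number of TRs (>= order + 1).
#' @param order polynomial order (3 by default).
#' @return numeric matrix nTr x (order + 1) with columns P0..Porder.
#' @examples
#' L <- legendreDrift(120, 3)
#' @export
legendreDrift <- function(nTr, order = 3) {
    if (nTr < order + 1) stop("nTr must be at least order + 1")
    x <- if (nTr == 1) 0 else seq(-1, 1, length.out = nTr)
    P <- matrix(0, nTr, order + 1)
    P[, 1] <- 1
    if (order >= 1) P[, 2] <- x
    if (order >= 2)
        for (k in 2:order)   # Bonnet recurrence
            P[, k + 1] <- ((2 * k - 1) * x * P[, k] -
                           (k - 1) * P[, k - 1]) / k
    colnames(P) <- paste0("P", 0:order)
    P
}

#' Leading and lagging copies of the motion regressors
#'
#' Each of the seven motion series (six rigid parameters plus total
#' displacement) contributes four regressors: a temporally leading copy
#' (-1 TR) and lagging copies at 0, +1 and +2 TRs, to absorb the prolonged
#' effect of autocorrelated movement on the BOLD signal. A lead of -1
#' places the value observed at TR t at row t - 1; a lag of +k places it at
#' row t + k. Out-of-range rows replicate the boundary sample.
#'
#' @param motion a \linkS4class{MotionSeries}.
#' @return numeric matrix TRs x 28 with columns
#'   \code{<component>_lag<l>}.
#' @export
laggedMotionRegressors <- function(motion) {
    stopifnot(is(motion, "MotionSeries"))
    base <- cbind(motion@params, total_disp = motion@totalDisplacement)
    if (ncol(base) != 7) stop("expected 7 motion components")
    nTr <- nrow(base)
    lags <- c(-1L, 0L, 1L, 2L)
    out <- matrix(0, nTr, 28)
    nm <- character(28)
    k <- 0L
    for (j in seq_len(7)) for (l in lags) {
        k <- k + 1L
        src <- pmin(pmax(seq_len(nTr) - l, 1L), nTr)
        out[, k] <- base[src, j]
        nm[k] <- sprintf("%s_lag%+d", colnames(base)[j], l)
    }
    colnames(out) <- nm
    out
}

#' Framewise displacement from rigid motion parameters
#'
#' The Euclidean norm of the time derivative of the six-parameter motion
#' series, with rotations (degrees) converted to arc length at a stated
#' head radius. The first TR has no predecessor and is assigned 0.
#'
#' @param params numeric matrix TRs x 6 (3 translations mm, 3 rotations
#'   degrees), or a \linkS4class{MotionSeries}.
#' @param headRadiusMm head radius for the rotation arc length (50 mm).
#' @return list with \code{fd} (per-TR series, mm) and \code{meanFd}.
#' @export
framewiseDisplacement <- function(params, headRadiusMm = 50) {
    if (is(params, "MotionSeries")) params <- params@params
    stopifnot(ncol(params) == 6, nrow(params) >= 2)
    if (!all(is.finite(params))) stop("motion parameters must be finite")
    d <- diff(params)
    d[, 4:6] <- d[, 4:6] * pi / 180 * headRadiusMm
    fd <- c(0, sqrt(rowSums(d^2)))
    list(fd = fd, meanFd = mean(fd))
}

#' FIR design matrix for trial-average deconvolution
#'
#' Builds the session design: one 0/1 finite-impulse-response column per
#' condition x hemifield x lag (the lag window is the trial duration plus
#' 15 TRs, anchored at the encoding saccade), third-order Legendre drift
#' per run, and the 28 lead/lag motion regressors. All trials of a cell
#' enter its FIR columns, including incorrect ones.
#'
#' @param design a \linkS4class{TaskDesign}.
#' @param motion a \linkS4class{MotionSeries} for the concatenated
#'   session, or NULL to omit motion columns.
#' @param driftOrder Legendre drift order per run.
#' @return list with \code{X} (TRs x p matrix), \code{roles} (character
#'   per column: "fir", "drift" or "motion"), \code{cells} (data.frame of
#'   condition cells with their lag counts) and \code{firIndex} (named
#'   list mapping cell label to its column indices).
#' @export
firDesign <- function(design, motion = NULL, driftOrder = 3) {
    stopifnot(is(design, "TaskDesign"))
    trials <- design@trials
    nTr <- design@nTrPerRun
    nTot <- nTr * design@nRuns
    tr <- design@trSeconds
    cells <- unique(trials[, c("presentation_s", "delay_s", "hemifield")])
    cells <- cells[order(cells$presentation_s, cells$delay_s,
                         cells$hemifield), ]
    rownames(cells) <- NULL
    cells$durTr <- as.integer(round((cells$presentation_s +
                                     cells$delay_s) / tr))
    cells$nLags <- cells$durTr + 15L
    cells$label <- sprintf("p%g_d%g_%s", cells$presentation_s,
                           cells$delay_s,
                           ifelse(cells$hemifield > 0, "R", "L"))
    firCols <- list()
    firIndex <- list()
    roles <- character(0)
    nm <- character(0)
    for (ci in seq_len(nrow(cells))) {
        sel <- trials$presentation_s == cells$presentation_s[ci] &
            trials$delay_s == cells$delay_s[ci] &
            trials$hemifield == cells$hemifield[ci]
        onsets <- trials$encode_tr[sel] + (trials$run[sel] - 1L) * nTr
        block <- matrix(0, nTot, cells$nLags[ci])
        for (lag in seq_len(cells$nLags[ci]) - 1L) {
            at <- onsets + lag
            at <- at[at >= 1 & at <= nTot]
            block[at, lag + 1L] <- 1
        }
        colnames(block) <- sprintf("%s_lag%02d", cells$label[ci],
                                   seq_len(cells$nLags[ci]) - 1L)
        firCols[[ci]] <- block
        firIndex[[cells$label[ci]]] <-
            length(nm) + seq_len(cells$nLags[ci])
        nm <- c(nm, colnames(block))
        roles <- c(roles, rep("fir", cells$nLags[ci]))
    }
    X <- do.call(cbind, firCols)
    ## per-run drift blocks
    L <- legendreDrift(nTr, driftOrder)
    for (r in seq_len(design@nRuns)) {
        block <- matrix(0, nTot, ncol(L))
        block[(r - 1L) * nTr + seq_len(nTr), ] <- L
        colnames(block) <- sprintf("drift_run%d_%s", r, colnames(L))
        X <- cbind(X, block)
        roles <- c(roles, rep("drift", ncol(L)))
    }
    if (!is.null(motion)) {
        M <- laggedMotionRegressors(motion)
        if (nrow(M) != nTot)
            stop("motion series length must match the design")
        X <- cbind(X, M)
        roles <- c(roles, rep("motion", ncol(M)))
    }
    list(X = X, roles = roles, cells = cells, firIndex = firIndex)
}

#' FIR deconvolution of a whole-brain series
#'
#' Ordinary least squares per voxel with the shared FIR design. The
#' per-cell trial-average coefficient maps are rescaled by dividing each
#' voxel's coefficients by the standard deviation of that voxel's
#' regression residuals; the residual series itself is returned unscaled
#' together with the per-voxel residual SD.
#'
#' @param series a \linkS4class{VolumeSeries} (runs concatenated).
#' @param design the result of \code{\link{firDesign}}.
#' @return list with \code{averages}: named list of voxels x lags scaled
#'   coefficient matrices (one per condition x hemifield cell),
#'   \code{averagesUnscaled}: the same before residual-SD scaling,
#'   \code{residuals}: a \linkS4class{ResidualSeries}, \code{motionCoef}:
#'   voxels x 28 matrix of motion-regressor coefficients (or NULL),
#'   \code{r2}: per-voxel R-squared of the full design.
#' @export
firDeconvolve <- function(series, design) {
    stopifnot(is(series, "VolumeSeries"))
    X <- design$X
    Y <- t(series@data)                       # TRs x voxels
    if (nrow(X) != nrow(Y))
        stop("design rows must equal the series TR count")
    B <- olsCoef(X, Y)                        # p x voxels
    R <- Y - X %*% B
    dfResid <- nrow(X) - ncol(X)
    residSd <- sqrt(colSums(R^2) / dfResid)
    averages <- list()
    averagesUnscaled <- list()
    for (lab in names(design$firIndex)) {
        cf <- t(B[design$firIndex[[lab]], , drop = FALSE]) # voxels x lags
        averagesUnscaled[[lab]] <- cf
        averages[[lab]] <- cf / residSd
    }
    motionCoef <- NULL
    if (any(design$roles == "motion"))
        motionCoef <- t(B[design$roles == "motion", , drop = FALSE])
    ssTot <- colSums(sweep(Y, 2, colMeans(Y))^2)
    r2 <- 1 - colSums(R^2) / ssTot
    residuals <- new("ResidualSeries", data = t(R), mask = series@mask,
                     trSeconds = series@trSeconds, residSd = residSd)
    list(averages = averages, averagesUnscaled = averagesUnscaled,
         residuals = residuals, motionCoef = motionCoef, r2 = r2,
         cells = design$cells)
}
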