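#' Project a whole-brain volume onto the brain states
#'
#' Vectorizes the volume and regresses it across voxels on the design
#' made of the six brain-state patterns and the nuisance templates fit
#' jointly, returning the per-component weights and the residual volume.
#' A rank-deficient design raises an error naming the collinear columns.
#'
#' @param volume a \linkS4class{MaskedVolume} or numeric voxel vector.
#' @param states a \linkS4class{BrainStateSet}.
#' @param nuisance a \linkS4class{NuisanceSet} (or NULL for states only).
#' @return list with \code{weights} (named numeric; states first) and
#'   \code{residual} (numeric voxel vector).
#' @export
projectVolume <- function(volume, states, nuisance = NULL) {
    v <- if (is(volume, "MaskedVolume")) volume@values else
        as.numeric(volume)
    D <- .projectionDesign(states, nuisance)
    w <- drop(olsCoef(D, v))
    list(weights = w, residual = v - drop(D %*% w))
}

.projectionDesign <- function(states, nuisance) {
    D <- states@patterns
    if (!is.null(nuisance)) {
        stopifnot(nVoxels(nuisance@mask) == nrow(D))
        T2 <- nuisance@templates
        colnames(T2) <- nuisance@labels
        D <- cbind(D, T2)
    }
    D
}

#' Time course of brain-state expression or fluctuation
#'
#' Applies \code{\link{projectVolume}} to every TR of a series and orders
#' the weights in time. Run on an average trial time series this yields
#' the expression time course of each state; run on a residual series it
#' yields the fluctuation time course, where positive values mean a state
#' was present to a greater extent than average at that TR.
#'
#' @param series a \linkS4class{VolumeSeries}.
#' @param states a \linkS4class{BrainStateSet}.
#' @param nuisance a \linkS4class{NuisanceSet} or NULL.
#' @param zscore if TRUE, each component row is temporally z-scored over
#'   the session (the convention for fluctuation series).
#' @return an \linkS4class{ExpressionSeries}; rows are the six states
#'   followed by the nuisance components.
#' @export
expressionTimecourse <- function(series, states, nuisance = NULL,
                                 zscore = FALSE) {
    D <- .projectionDesign(states, nuisance)
    W <- olsCoef(D, series@data)          # p x TRs
    if (zscore) W <- t(apply(W, 1, function(r) {
        s <- sd(r)
        if (!is.finite(s) || s == 0) r - mean(r) else (r - mean(r)) / s
    }))
    new("ExpressionSeries", weights = W, zscored = zscore,
        trSeconds = series@trSeconds)
}
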