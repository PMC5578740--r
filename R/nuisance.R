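#' Motion-artifact templates from lagged motion coefficient maps
#'
#' Each of the 28 lagged-motion coefficient maps (7 components x 4
#' lead/lags, averaged across sessions) is divided voxel-wise by the
#' residual SD, centered to zero spatial mean and scaled to a common
#' vector magnitude; a principal component decomposition across the 28
#' maps (uncentered, since the maps are already spatial-mean-centered)
#' then yields the smallest set of orthonormal template volumes whose
#' cumulative explained variance exceeds \code{varianceTarget}.
#'
#' @param coefMaps voxels x m matrix of motion coefficient maps (m >= 2;
#'   28 in the standard design).
#' @param residSd per-voxel residual SD (numeric or
#'   \linkS4class{MaskedVolume}).
#' @param varianceTarget cumulative explained-variance target (0.90).
#' @return list with \code{templates} (voxels x k orthonormal matrix),
#'   \code{varianceCaptured} (per-template fractions) and \code{k}.
#' @export
motionTemplates <- function(coefMaps, residSd, varianceTarget = 0.90) {
    if (is(residSd, "MaskedVolume")) residSd <- residSd@values
    coefMaps <- as.matrix(coefMaps)
    if (ncol(coefMaps) < 2) stop("need at least 2 coefficient maps")
    M <- coefMaps / residSd
    M <- sweep(M, 2, colMeans(M))
    norms <- sqrt(colSums(M^2))
    norms[norms == 0] <- 1
    M <- sweep(M, 2, norms, "/")
    sv <- svd(M)
    evFrac <- sv$d^2 / sum(sv$d^2)
    k <- which(cumsum(evFrac) > varianceTarget)[1]
    list(templates = sv$u[, seq_len(k), drop = FALSE],
         varianceCaptured = evFrac[seq_len(k)], k = k)
}

#' Spatial constant and gradient nuisance templates
#'
#' Builds the eight trivial-mode templates: x, y and z gradients (voxel
#' coordinates relative to the mask's center of mass, zero outside the
#' mask), their three pairwise products, a whole-volume constant and a
#' state-mask constant.
#'
#' @param mask a \linkS4class{BrainMask}.
#' @param stateMask optional logical per-voxel state-mask indicator (the
#'   whole mask when NULL).
#' @return voxels x 8 matrix with columns grad_x, grad_y, grad_z,
#'   grad_xy, grad_xz, grad_yz, const_whole, const_state.
#' @export
spatialGradientTemplates <- function(mask, stateMask = NULL) {
    co <- sweep(mask@coords, 2, colMeans(mask@coords))
    if (any(apply(co, 2, function(x) all(abs(x) < 1e-12))))
        warning("degenerate mask geometry: voxels are coplanar")
    if (is.null(stateMask)) stateMask <- rep(TRUE, nVoxels(mask))
    out <- cbind(grad_x = co[, 1], grad_y = co[, 2], grad_z = co[, 3],
                 grad_xy = co[, 1] * co[, 2],
                 grad_xz = co[, 1] * co[, 3],
                 grad_yz = co[, 2] * co[, 3],
                 const_whole = rep(1, nVoxels(mask)),
                 const_state = as.numeric(stateMask))
    out
}

#' Assemble the full spatial nuisance regressor set
#'
#' Combines the motion templates with the constant and gradient templates
#' into the nuisance set fit alongside the six brain states in every
#' projection (with 11 motion templates this is the 19-member set).
#'
#' @param motion the result of \code{\link{motionTemplates}}, or NULL for
#'   a nuisance set without motion templates.
#' @param mask a \linkS4class{BrainMask}.
#' @param stateMask optional logical state-mask indicator.
#' @return a \linkS4class{NuisanceSet}.
#' @export
buildNuisanceSet <- function(motion, mask, stateMask = NULL) {
    grad <- spatialGradientTemplates(mask, stateMask)
    ## without a distinct state mask the two constants coincide; keep one
    ## so the projection design stays full rank
    if (identical(unname(grad[, "const_whole"]),
                  unname(grad[, "const_state"])))
        grad <- grad[, colnames(grad) != "const_state", drop = FALSE]
    if (is.null(motion)) {
        templates <- grad
        varCap <- numeric(0)
    } else {
        mt <- motion$templates
        colnames(mt) <- sprintf("motion_pc%02d", seq_len(ncol(mt)))
        templates <- cbind(mt, grad)
        varCap <- motion$varianceCaptured
    }
    new("NuisanceSet", templates = unname(templates),
        labels = colnames(templates), varianceCaptured = varCap,
        mask = mask)
}
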