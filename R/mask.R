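#' Construct a mirror-paired rectangular brain mask
#'
#' Builds a \linkS4class{BrainMask} with \code{nPerHemisphere} voxels in
#' each hemisphere, laid out on a small 3D grid with two slabs per
#' hemisphere along x. Voxel i of the right hemisphere is paired with voxel
#' i of the left, and the x coordinate negates under the pairing, so the
#' pairing is an exact geometric mirror. The symmetrization contract of the
#' state-extraction step only needs this pairing, not a registration-based
#' reflection.
#'
#' @param nPerHemisphere voxels per hemisphere (>= 10).
#' @param maskId identifier string.
#' @return a \linkS4class{BrainMask}.
#' @examples
#' m <- makeMirroredMask(100)
#' nVoxels(m)  # 200
#' @export
makeMirroredMask <- function(nPerHemisphere, maskId = "synthetic") {
    if (nPerHemisphere < 10)
        stop("need at least 10 voxels per hemisphere")
    n <- as.integer(nPerHemisphere)
    ## two x-slabs per hemisphere; y, z tile the remainder
    ny <- max(2L, as.integer(ceiling(sqrt(n / 2))))
    nz <- as.integer(ceiling(n / (2 * ny)))
    grid <- expand.grid(s = 1:2, y = seq_len(ny), z = seq_len(nz))
    grid <- grid[order(grid$z, grid$y, grid$s), ][seq_len(n), ]
    dim3 <- c(4L, ny, nz)
    ## x index: left hemisphere slabs 1-2 (x = -2, -1), right 3-4 (x = 1, 2)
    xr <- 2L + grid$s           # right-hemisphere x index
    xl <- 3L - grid$s           # mirrored left-hemisphere x index
    linIdx <- function(x, y, z) (z - 1L) * dim3[1] * dim3[2] +
        (y - 1L) * dim3[1] + x
    activeR <- linIdx(xr, grid$y, grid$z)
    activeL <- linIdx(xl, grid$y, grid$z)
    coordsR <- cbind(x = c(1, 2)[grid$s], y = grid$y, z = grid$z)
    coordsL <- cbind(x = -c(1, 2)[grid$s], y = grid$y, z = grid$z)
    new("BrainMask",
        dim = dim3,
        active = as.integer(c(activeR, activeL)),
        coords = rbind(coordsR, coordsL),
        pairing = as.integer(c(n + seq_len(n), seq_len(n))),
        maskId = maskId)
}

#' Restrict a mask to a voxel subset
#'
#' The subset is symmetrized first (a voxel is kept only if its mirror
#' partner is kept) so the mirror pairing remains an involution on the
#' result.
#'
#' @param mask a \linkS4class{BrainMask}.
#' @param keep logical per-voxel inclusion vector.
#' @param maskId identifier for the restricted mask.
#' @return a \linkS4class{BrainMask} on the kept voxels.
#' @export
subsetMask <- function(mask, keep, maskId = paste0(mask@maskId, "_sub")) {
    stopifnot(length(keep) == nVoxels(mask))
    keep <- keep & keep[mask@pairing]
    if (!any(keep)) stop("mask subset is empty")
    idx <- which(keep)
    remap <- integer(nVoxels(mask))
    remap[idx] <- seq_along(idx)
    new("BrainMask",
        dim = mask@dim,
        active = mask@active[idx],
        coords = mask@coords[idx, , drop = FALSE],
        pairing = remap[mask@pairing[idx]],
        maskId = maskId)
}

## Embed masked values in the full 3D array (fill value elsewhere).
maskedToArray <- function(mask, values, fill = 0) {
    a <- array(fill, dim = mask@dim)
    a[mask@active] <- values
    a
}

## Extract masked values from a 3D array.
arrayToMasked <- function(mask, a) as.numeric(a[mask@active])

#' Build a BrainMask from a NIfTI mask volume
#'
#' Voxels with value > 0 enter the mask. The mirror pairing is geometric
#' reflection of the first array axis (i -> nx + 1 - i); voxels whose
#' reflected partner is outside the mask are dropped so the pairing is an
#' involution.
#'
#' @param path path to a NIfTI mask file.
#' @param maskId identifier; defaults to the file name.
#' @return a \linkS4class{BrainMask}.
#' @export
maskFromNifti <- function(path, maskId = basename(path)) {
    img <- RNifti::readNifti(path)
    a <- array(as.numeric(img > 0), dim = dim(img)[1:3])
    nx <- dim(a)[1]
    idx <- which(a > 0, arr.ind = TRUE)
    mirrored <- cbind(nx + 1L - idx[, 1], idx[, 2], idx[, 3])
    lin <- function(m) (m[, 3] - 1L) * nx * dim(a)[2] +
        (m[, 2] - 1L) * nx + m[, 1]
    inMask <- lin(mirrored) %in% lin(idx)
    idx <- idx[inMask, , drop = FALSE]
    ord <- order(idx[, 3], idx[, 2], idx[, 1])
    idx <- idx[ord, , drop = FALSE]
    active <- lin(idx)
    pairing <- match(lin(cbind(nx + 1L - idx[, 1], idx[, 2], idx[, 3])),
                     active)
    coords <- cbind(x = idx[, 1] - (nx + 1) / 2, y = idx[, 2], z = idx[, 3])
    new("BrainMask", dim = as.integer(dim(a)), active = as.integer(active),
        coords = coords, pairing = as.integer(pairing), maskId = maskId)
}
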