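#' Generate ground-truth brain-state patterns
#'
#' Draws six smooth random whole-brain patterns on a mirror-paired mask:
#' for each of the three task states, a mean component that is exactly
#' symmetric under the left/right pairing and a spatial component that is
#' exactly antisymmetric. Mirroring makes mean and spatial components
#' mutually orthogonal; the mean components are additionally
#' orthogonalized across states (VME, then maintenance, then retrieval)
#' and likewise the spatial components, mirroring the sequential
#' orthogonalization that defines the canonical states, so the six
#' ground-truth patterns are exactly orthonormal. Each pattern is
#' centered to zero spatial mean and scaled to unit vector norm.
#' Smoothness is imposed by Gaussian kernel smoothing along the
#' within-hemisphere voxel index.
#'
#' @param nVoxelsPerHemisphere voxels per hemisphere (>= 10).
#' @param smoothness kernel SD in voxel units.
#' @param seed integer seed.
#' @param mask optionally, an existing mirror-paired \linkS4class{BrainMask}
#'   to draw the patterns on (its per-hemisphere voxel count then wins).
#' @return a \linkS4class{BrainStateSet} with ground-truth patterns.
#' @examples
#' truthStates <- generateStatePatterns(100, seed = 1)
#' @export
generateStatePatterns <- function(nVoxelsPerHemisphere, smoothness = 5,
                                  seed = NULL, mask = NULL) {
    if (is.null(mask)) mask <- makeMirroredMask(nVoxelsPerHemisphere)
    n <- nVoxels(mask) %/% 2L
    if (2L * n < 6L)
        stop("degenerate basis: need at least 6 voxels for 6 components")
    half <- seq_len(n)                 # right hemisphere comes first
    smoothField <- function() {
        pad <- max(1L, as.integer(ceiling(3 * smoothness)))
        x <- rnorm(n + 2L * pad)
        if (smoothness > 0) {
            k <- exp(-0.5 * (seq(-pad, pad) / smoothness)^2)
            x <- as.numeric(stats::filter(x, k / sum(k), sides = 2))
        }
        x[pad + half]
    }
    pats <- withSeed(seed, {
        out <- matrix(0, nVoxels(mask), 6,
                      dimnames = list(NULL, .stateLabels))
        for (s in 1:3) {
            fMean <- smoothField()
            fSpat <- smoothField()
            v <- numeric(nVoxels(mask))
            ## symmetric mean component: same field in both hemispheres
            v[half] <- fMean; v[mask@pairing[half]] <- fMean
            out[, 2L * s - 1L] <- centerUnitNorm(v)
            ## antisymmetric spatial component: sign flips across midline
            v[half] <- fSpat; v[mask@pairing[half]] <- -fSpat
            ## spatial mean is already 0 by antisymmetry; centering is a
            ## no-op but keeps the contract uniform
            out[, 2L * s] <- centerUnitNorm(v)
        }
        ## Gram-Schmidt across states within the mean and spatial
        ## families (symmetry classes are preserved: a combination of
        ## symmetric fields is symmetric, likewise antisymmetric)
        for (fam in list(c(1, 3, 5), c(2, 4, 6)))
            for (j in seq_along(fam)[-1]) {
                for (k in fam[seq_len(j - 1)])
                    out[, fam[j]] <- out[, fam[j]] -
                        sum(out[, fam[j]] * out[, k]) * out[, k]
                out[, fam[j]] <- centerUnitNorm(out[, fam[j]])
            }
        out
    })
    if (qr(pats)$rank < 6L)
        stop("degenerate basis: generated patterns are not independent")
    new("BrainStateSet", patterns = pats, mask = mask, lagTr = 4L,
        provenance = "synthetic ground truth")
}
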