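#' Number of voxels in a masked object
#' @param x a BrainMask or an object carrying one.
#' @return integer voxel count.
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' @describeIn nVoxels voxel count of a mask
#' @export
setMethod("nVoxels", "BrainMask", function(x) length(x@active))

#' @describeIn nVoxels voxel count of a volume
#' @export
setMethod("nVoxels", "MaskedVolume", function(x) length(x@values))

#' @describeIn nVoxels voxel count of a series
#' @export
setMethod("nVoxels", "VolumeSeries", function(x) nrow(x@data))

#' @describeIn nVoxels voxel count of a state set
#' @export
setMethod("nVoxels", "BrainStateSet", function(x) nrow(x@patterns))

#' Voxel values of a masked volume
#' @param x a MaskedVolume.
#' @return numeric vector of per-voxel values.
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))

#' @describeIn voxelValues values of a volume
#' @export
setMethod("voxelValues", "MaskedVolume", function(x) x@values)

#' Data matrix (voxels x TRs) of a series
#' @param x a VolumeSeries.
#' @return numeric matrix.
#' @export
setGeneric("seriesData", function(x) standardGeneric("seriesData"))

#' @describeIn seriesData data of a series
#' @export
setMethod("seriesData", "VolumeSeries", function(x) x@data)

#' The BrainMask an object lives on
#' @param x a masked object.
#' @return a BrainMask.
#' @export
setGeneric("brainMask", function(x) standardGeneric("brainMask"))

#' @describeIn brainMask mask of a volume
#' @export
setMethod("brainMask", "MaskedVolume", function(x) x@mask)

#' @describeIn brainMask mask of a series
#' @export
setMethod("brainMask", "VolumeSeries", function(x) x@mask)

#' @describeIn brainMask mask of a state set
#' @export
setMethod("brainMask", "BrainStateSet", function(x) x@mask)

#' @describeIn brainMask mask of a nuisance set
#' @export
setMethod("brainMask", "NuisanceSet", function(x) x@mask)

#' State pattern matrix (voxels x 6) of a BrainStateSet
#' @param x a BrainStateSet.
#' @return numeric matrix with the canonical column order.
#' @export
setGeneric("statePatterns", function(x) standardGeneric("statePatterns"))

#' @describeIn statePatterns patterns of a state set
#' @export
setMethod("statePatterns", "BrainStateSet", function(x) x@patterns)

#' Canonical state component labels
#' @return character(6): vme/maint/retr x mean/spatial.
#' @export
stateLabels <- function() .stateLabels

#' Template matrix of a NuisanceSet
#' @param x a NuisanceSet.
#' @return numeric matrix voxels x k with labelled columns.
#' @export
setGeneric("templateVolumes", function(x) standardGeneric("templateVolumes"))

#' @describeIn templateVolumes templates of a nuisance set
#' @export
setMethod("templateVolumes", "NuisanceSet",
          function(x) structure(x@templates,
                                dimnames = list(NULL, x@labels)))

#' State-attributable and total sums of squares
#'
#' \code{ssBrain} is the sum of the three state component sums of squares
#' (exact by construction); \code{totalBrainStateVariability} is the ratio
#' SS_brain / (SS_brain + SS_error); \code{motionTemplateVariance} is
#' SS_motion / (SS_brain + SS_error).
#'
#' @param x a VarianceDecomposition.
#' @return a numeric scalar.
#' @export
setGeneric("ssBrain", function(x) standardGeneric("ssBrain"))

#' @describeIn ssBrain total state-attributable SS
#' @export
setMethod("ssBrain", "VarianceDecomposition",
          function(x) x@ssVme + x@ssMaint + x@ssRetrieval)

#' @rdname ssBrain
#' @export
setGeneric("totalBrainStateVariability",
           function(x) standardGeneric("totalBrainStateVariability"))

#' @describeIn ssBrain the brain-state variability ratio
#' @export
setMethod("totalBrainStateVariability", "VarianceDecomposition",
          function(x) ssBrain(x) / (ssBrain(x) + x@ssError))

#' @rdname ssBrain
#' @export
setGeneric("motionTemplateVariance",
           function(x) standardGeneric("motionTemplateVariance"))

#' @describeIn ssBrain the motion-template variance ratio
#' @export
setMethod("motionTemplateVariance", "VarianceDecomposition",
          function(x) x@ssMotion / (ssBrain(x) + x@ssError))

setMethod("show", "BrainMask", function(object) {
    cat("BrainMask", object@maskId, "with", nVoxels(object),
        "voxels in a", paste(object@dim, collapse = " x "),
        "grid (mirror-paired)\n")
})

setMethod("show", "MaskedVolume", function(object) {
    cat("MaskedVolume on", object@mask@maskId, "-", nVoxels(object),
        "voxels; range",
        paste(signif(range(object@values), 4), collapse = " .. "), "\n")
})

setMethod("show", "VolumeSeries", function(object) {
    cat(class(object), "on", object@mask@maskId, "-", nVoxels(object),
        "voxels x", ncol(object@data), "TRs (TR =",
        object@trSeconds, "s)\n")
})

setMethod("show", "MotionSeries", function(object) {
    cat("MotionSeries with", nrow(object@params),
        "TRs; mean total displacement",
        signif(mean(object@totalDisplacement), 4), "mm\n")
})

setMethod("show", "TaskDesign", function(object) {
    cat("TaskDesign:", nrow(object@trials), "trials over", object@nRuns,
        "runs of", object@nTrPerRun, "TRs (TR =", object@trSeconds,
        "s)\n")
})

setMethod("show", "BrainStateSet", function(object) {
    cat("BrainStateSet on", object@mask@maskId, "-", nVoxels(object),
        "voxels, lag", object@lagTr, "TRs\n  components:",
        paste(colnames(object@patterns), collapse = ", "), "\n")
})

setMethod("show", "NuisanceSet", function(object) {
    nm <- sum(grepl("^motion_pc", object@labels))
    cat("NuisanceSet with", length(object@labels), "templates (",
        nm, "motion +", length(object@labels) - nm, "constant/gradient )\n")
})

setMethod("show", "VarianceDecomposition", function(object) {
    cat("VarianceDecomposition over", object@nTrUsed, "TRs (window",
        paste(range(object@window), collapse = ".."), "around each MGS)\n")
    cat(sprintf("  SS_brain = %.4g (VME %.4g + Maint %.4g + Retr %.4g)\n",
                ssBrain(object), object@ssVme, object@ssMaint,
                object@ssRetrieval))
    cat(sprintf("  total brain state variability = %.4g\n",
                totalBrainStateVariability(object)))
    cat(sprintf("  motion template variance      = %.4g\n",
                motionTemplateVariance(object)))
})

setMethod("show", "MechanismSim", function(object) {
    cat("MechanismSim mode =", object@mode, "with", length(object@rtMs),
        "trials;\n  terminal integrals fast/slow:",
        signif(object@integralFast[length(object@integralFast)], 4), "/",
        signif(object@integralSlow[length(object@integralSlow)], 4), "\n")
})

setMethod("show", "TrajectoryFit", function(object) {
    cat("TrajectoryFit (", object@form, ") AIC =", signif(object@aic, 6),
        "\n")
    print(signif(object@fixef, 4))
})
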