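#' @import methods
#' @importFrom stats rnorm sd var coef lm lm.fit optimize quantile median
#'   qnorm pnorm cor cor.test logLik AIC fitted resid setNames runif rlnorm
#'   dgamma p.adjust aggregate as.formula simulate predict
NULL

## Canonical component ordering used throughout the package: three task
## states (visuomotor/encoding, maintenance, retrieval), each split into a
## hemifield-average ("mean") and a right-minus-left ("spatial") component.
.stateLabels <- c("vme_mean", "vme_spatial",
                  "maint_mean", "maint_spatial",
                  "retr_mean", "retr_spatial")

#' BrainMask: voxel bookkeeping for masked whole-brain data
#'
#' A \code{BrainMask} fixes the set of voxels all masked objects live on,
#' their 3D coordinates (voxel units), and a left/right mirror pairing used
#' to impose and test the symmetry of brain-state patterns. The pairing is an
#' involution on voxel indices: \code{pairing[pairing[i]] == i}.
#'
#' @slot dim integer(3), dimensions of the enclosing 3D array.
#' @slot active integer, linear indices of in-mask voxels in the 3D array.
#' @slot coords numeric matrix (voxels x 3) of voxel coordinates; the x
#'   coordinate changes sign under the mirror pairing.
#' @slot pairing integer permutation mapping each voxel to its mirror voxel.
#' @slot maskId character identifier; objects sharing data must share it.
#' @export
setClass("BrainMask",
         representation(dim = "integer", active = "integer",
                        coords = "matrix", pairing = "integer",
                        maskId = "character"))

setValidity("BrainMask", function(object) {
    n <- length(object@active)
    if (nrow(object@coords) != n)
        return("coords must have one row per active voxel")
    if (length(object@pairing) != n)
        return("pairing must have one entry per active voxel")
    p <- object@pairing
    if (!all(p[p] == seq_len(n)))
        return("pairing must be an involution on the mask")
    if (any(abs(object@coords[p, 1] + object@coords[, 1]) > 1e-8))
        return("x coordinates must negate under the mirror pairing")
    TRUE
})

#' MaskedVolume: a single whole-brain volume restricted to a mask
#'
#' @slot values numeric vector, one value per mask voxel (a.u.).
#' @slot mask the \linkS4class{BrainMask} the values live on.
#' @export
setClass("MaskedVolume",
         representation(values = "numeric", mask = "BrainMask"))

setValidity("MaskedVolume", function(object) {
    if (length(object@values) != length(object@mask@active))
        return("values length must equal the mask voxel count")
    if (!all(is.finite(object@values)))
        return("values must be finite")
    TRUE
})

#' VolumeSeries: a voxels x TRs matrix on a fixed mask
#'
#' @slot data numeric matrix, voxels x TRs (a.u.).
#' @slot mask the \linkS4class{BrainMask}.
#' @slot trSeconds repetition time in seconds (1.5 for this task).
#' @export
setClass("VolumeSeries",
         representation(data = "matrix", mask = "BrainMask",
                        trSeconds = "numeric"))

setValidity("VolumeSeries", function(object) {
    if (nrow(object@data) != length(object@mask@active))
        return("data must have one row per mask voxel")
    if (!all(is.finite(object@data)))
        return("data must be finite")
    if (object@trSeconds <= 0) return("trSeconds must be positive")
    TRUE
})

#' ResidualSeries: deconvolution residuals with their per-voxel SD
#'
#' @slot residSd numeric per-voxel residual standard deviation.
#' @export
setClass("ResidualSeries", contains = "VolumeSeries",
         representation(residSd = "numeric"))

#' MotionSeries: rigid-body motion parameters per TR
#'
#' Six rigid components (3 translations in mm, 3 rotations in degrees) plus
#' the per-TR total displacement (Euclidean norm of the time derivative of
#' the six-parameter series, rotations expressed as arc length).
#'
#' @slot params numeric matrix TRs x 6 with columns trans_x, trans_y,
#'   trans_z, rot_x, rot_y, rot_z.
#' @slot totalDisplacement numeric, nonnegative, one value per TR.
#' @export
setClass("MotionSeries",
         representation(params = "matrix", totalDisplacement = "numeric"))

setValidity("MotionSeries", function(object) {
    if (ncol(object@params) != 6) return("params must have 6 columns")
    if (length(object@totalDisplacement) != nrow(object@params))
        return("totalDisplacement must have one value per TR")
    if (any(object@totalDisplacement < 0))
        return("totalDisplacement must be nonnegative")
    TRUE
})

#' TaskDesign: trial layout of a memory-guided saccade session
#'
#' Trials present a peripheral target at one of six locations (plus/minus 3,
#' 6 or 9 degrees on the horizontal meridian) for 1.5 or 3 s, followed by a
#' 1.5 or 9 s delay and a memory-guided saccade on fixation offset.
#'
#' @slot trials data.frame with columns run, presentation_s, delay_s,
#'   hemifield (-1/+1), eccentricity_deg, eccentricity (code 1-3),
#'   encode_tr, mgs_tr (run-local, 1-based TR of the encoding saccade and
#'   the MGS).
#' @slot nRuns integer number of runs.
#' @slot nTrPerRun integer TRs per run.
#' @slot trSeconds numeric, TR duration in seconds.
#' @export
setClass("TaskDesign",
         representation(trials = "data.frame", nRuns = "integer",
                        nTrPerRun = "integer", trSeconds = "numeric"))

setValidity("TaskDesign", function(object) {
    tr <- object@trials
    need <- c("run", "presentation_s", "delay_s", "hemifield",
              "eccentricity_deg", "eccentricity", "encode_tr", "mgs_tr")
    if (!all(need %in% names(tr)))
        return(paste("trials must contain columns:",
                     paste(need, collapse = ", ")))
    if (any(tr$encode_tr >= tr$mgs_tr))
        return("encode_tr must precede mgs_tr")
    combos <- unique(tr[, c("presentation_s", "delay_s")])
    if (nrow(combos) < 4)
        return("all four presentation x delay conditions must be present")
    for (r in unique(tr$run)) {
        tt <- tr[tr$run == r, ]
        tt <- tt[order(tt$encode_tr), ]
        if (nrow(tt) > 1) {
            gap <- tt$encode_tr[-1] - tt$mgs_tr[-nrow(tt)]
            if (any(gap < 15))
                return("inter-trial gap must be at least 15 TRs")
        }
        if (max(tt$mgs_tr) + 15 > object@nTrPerRun)
            return("trials (plus the 15 TR FIR tail) must fit in the run")
    }
    TRUE
})

#' GainGroundTruth: parameters of the synthetic gain-modulation model
#'
#' Each of the six state components is expressed on every trial with a
#' multiplicative gain drawn around its mean (1 for mean components, the
#' target hemifield sign for spatial components). Behavior is linearly
#' coupled to the gain deviations.
#'
#' @slot gainSd numeric(6), per-component SD of the trial gains.
#' @slot rtCoupling numeric(6), ms of reaction time per unit gain deviation.
#' @slot seCoupling numeric(6), degrees of saccadic error per unit gain
#'   deviation.
#' @slot rtBaseMs baseline reaction time (ms).
#' @slot rtNoiseSdMs residual RT noise SD (ms).
#' @slot seNoiseSdDeg residual SE noise SD (degrees).
#' @slot amplitude BOLD amplitude (a.u.) of a unit-norm pattern at gain 1.
#' @slot noiseSd i.i.d. BOLD noise SD (a.u.), must be positive.
#' @slot driftSd SD of per-voxel Legendre drift coefficients (a.u.).
#' @slot motionAmplitudeMm SD of the per-TR motion random-walk increments.
#' @slot motionArtifactScale BOLD a.u. per unit motion regressor.
#' @slot pIncorrect probability a trial is unmeasurable/incorrect.
#' @slot timingJitter logical; when TRUE the retrieval event is placed
#'   at the trial's actual response time (MGS TR plus the trial's RT
#'   deviation), adding the latency component of brain/behavior
#'   coupling on top of the amplitude component.
#' @export
setClass("GainGroundTruth",
         representation(gainSd = "numeric", rtCoupling = "numeric",
                        seCoupling = "numeric", rtBaseMs = "numeric",
                        rtNoiseSdMs = "numeric", seNoiseSdDeg = "numeric",
                        amplitude = "numeric", noiseSd = "numeric",
                        driftSd = "numeric", motionAmplitudeMm = "numeric",
                        motionArtifactScale = "numeric",
                        pIncorrect = "numeric",
                        timingJitter = "logical"))

setValidity("GainGroundTruth", function(object) {
    for (s in c("gainSd", "rtCoupling", "seCoupling"))
        if (length(slot(object, s)) != 6)
            return(paste(s, "must have length 6"))
    if (any(object@gainSd < 0)) return("gainSd must be nonnegative")
    if (object@noiseSd <= 0) return("noiseSd must be positive")
    if (object@pIncorrect < 0 || object@pIncorrect > 1)
        return("pIncorrect must lie in [0, 1]")
    TRUE
})

#' BrainStateSet: the six canonical brain-state patterns
#'
#' @slot patterns numeric matrix voxels x 6, columns in the canonical order
#'   vme_mean, vme_spatial, maint_mean, maint_spatial, retr_mean,
#'   retr_spatial; each pattern centered to zero spatial mean and unit norm.
#' @slot mask the \linkS4class{BrainMask}.
#' @slot lagTr hemodynamic lag used for epoch extraction (TRs).
#' @slot provenance free-text description of the source epochs.
#' @export
setClass("BrainStateSet",
         representation(patterns = "matrix", mask = "BrainMask",
                        lagTr = "integer", provenance = "character"))

setValidity("BrainStateSet", function(object) {
    if (nrow(object@patterns) != length(object@mask@active))
        return("patterns must have one row per mask voxel")
    if (!identical(colnames(object@patterns), .stateLabels))
        return(paste("pattern columns must be:",
                     paste(.stateLabels, collapse = ", ")))
    TRUE
})

#' NuisanceSet: spatial nuisance regressors fit alongside brain states
#'
#' Motion-artifact templates (principal components of the lagged-motion
#' coefficient maps) plus the whole-volume constant, a state-mask constant,
#' three linear spatial gradients and their three pairwise products.
#'
#' @slot templates numeric matrix voxels x k.
#' @slot labels character column labels; motion templates are named
#'   \code{motion_pcN}.
#' @slot varianceCaptured numeric, explained-variance fraction per motion
#'   template (empty when no motion templates are present).
#' @slot mask the \linkS4class{BrainMask}.
#' @export
setClass("NuisanceSet",
         representation(templates = "matrix", labels = "character",
                        varianceCaptured = "numeric", mask = "BrainMask"))

setValidity("NuisanceSet", function(object) {
    if (ncol(object@templates) != length(object@labels))
        return("labels must match template count")
    if (nrow(object@templates) != length(object@mask@active))
        return("templates must have one row per mask voxel")
    TRUE
})

#' ExpressionSeries: time courses of brain-state expression weights
#'
#' @slot weights numeric matrix components x TRs of regression weights; the
#'   six state components come first, nuisance weights after.
#' @slot zscored logical, whether rows were temporally z-scored.
#' @slot trSeconds TR duration (s).
#' @export
setClass("ExpressionSeries",
         representation(weights = "matrix", zscored = "logical",
                        trSeconds = "numeric"))

#' VarianceDecomposition: sums of squares of residual BOLD variability
#'
#' Defined over the TR window around each correct memory-guided saccade.
#' \code{ssBrain = ssVme + ssMaint + ssRetrieval} holds exactly because the
#' component sums of squares are computed on a sequentially orthonormalized
#' basis.
#'
#' @slot ssVme,ssMaint,ssRetrieval state-attributable sums of squares.
#' @slot ssMotion motion-template sum of squares.
#' @slot ssNuisanceOther remaining nuisance (constant/gradient) SS.
#' @slot ssError unexplained sum of squares.
#' @slot window integer TR offsets used around each MGS.
#' @slot nTrUsed number of TRs entering the decomposition.
#' @export
setClass("VarianceDecomposition",
         representation(ssVme = "numeric", ssMaint = "numeric",
                        ssRetrieval = "numeric", ssMotion = "numeric",
                        ssNuisanceOther = "numeric", ssError = "numeric",
                        window = "integer", nTrUsed = "integer"))

#' TrajectoryFit: developmental trajectory of a session-level measure
#'
#' @slot fixef named numeric fixed-effect estimates.
#' @slot fixefTable data.frame with estimate, std. error, t and p per term.
#' @slot subjectCoefs data.frame of per-subject coefficients.
#' @slot logLik,aic model fit statistics (ML).
#' @slot form "linear_age" or "inverse_age".
#' @slot endpointChange fitted value at age 8 minus at age 33 (fixed
#'   effects only).
#' @slot model the underlying fit object.
#' @export
setClass("TrajectoryFit",
         representation(fixef = "numeric", fixefTable = "data.frame",
                        subjectCoefs = "data.frame", logLik = "numeric",
                        aic = "numeric", form = "character",
                        endpointChange = "numeric", model = "ANY"))

#' SnippetStack: MGS-aligned windows of brain-state fluctuation
#'
#' @slot values numeric array trials x (2*halfWidth+1) x 6 of z-scored
#'   fluctuation values; relative TR 0 (the MGS) is the center column;
#'   out-of-run cells are NA.
#' @slot trials data.frame of per-trial metadata and behavior.
#' @slot halfWidth window half width in TRs.
#' @export
setClass("SnippetStack",
         representation(values = "array", trials = "data.frame",
                        halfWidth = "integer"))

setValidity("SnippetStack", function(object) {
    if (dim(object@values)[2] != 2L * object@halfWidth + 1L)
        return("values must have 2*halfWidth+1 relative-TR columns")
    if (dim(object@values)[1] != nrow(object@trials))
        return("values must have one row per trial")
    TRUE
})

#' MechanismSim: a latency/amplitude reaction-time simulation
#'
#' @slot mode "timing", "amplitude" or "mixed".
#' @slot rtMs simulated reaction times (ms).
#' @slot binSeconds time bin (s), 0.060 by default.
#' @slot meanSeries grand-mean HRF series across trials.
#' @slot residFast,residSlow mean residual series for the fast/slow RT
#'   halves (median split).
#' @slot integralFast,integralSlow cumulative time integrals of the two
#'   mean residual series.
#' @export
setClass("MechanismSim",
         representation(mode = "character", rtMs = "numeric",
                        binSeconds = "numeric", meanSeries = "numeric",
                        residFast = "numeric", residSlow = "numeric",
                        integralFast = "numeric", integralSlow = "numeric"))
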