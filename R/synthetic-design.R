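#' Build a memory-guided saccade task design
#'
#' Lays out trials for a session of the MGS task: every run contains a
#' balanced set of the four presentation x delay conditions
#' (presentation 1.5 or 3 s, delay 1.5 or 9 s) crossed with target
#' hemifield, with eccentricity cycling through 3, 6 and 9 degrees. The
#' encoding saccade TR and MGS TR are placed sequentially with a fixed
#' inter-trial gap; the run length leaves room for the 15 TR FIR tail after
#' the last MGS. The trial count per run and inter-trial interval are
#' configuration, with defaults chosen to fit runs of roughly 200 TRs.
#'
#' @param nRuns number of runs (3 by default).
#' @param trialsPerCell trials per condition x hemifield cell per run.
#' @param itiTr gap in TRs between a trial's MGS and the next encoding
#'   saccade (>= 15).
#' @param startTr TR of the first encoding saccade in each run.
#' @param trSeconds TR duration (s).
#' @param seed optional seed; when given, the trial order within each run
#'   is a seeded permutation, otherwise a fixed interleave.
#' @return a \linkS4class{TaskDesign}.
#' @examples
#' d <- mgsTaskDesign()
#' @export
mgsTaskDesign <- function(nRuns = 3, trialsPerCell = 1, itiTr = 16,
                          startTr = 5, trSeconds = 1.5, seed = NULL) {
    stopifnot(itiTr >= 15, startTr >= 1, trialsPerCell >= 1)
    cells <- expand.grid(presentation_s = c(1.5, 3.0),
                         delay_s = c(1.5, 9.0),
                         hemifield = c(-1, 1))
    eccLevels <- c(3, 6, 9)
    rows <- list()
    eccCounter <- 0L
    for (r in seq_len(nRuns)) {
        runTrials <- cells[rep(seq_len(nrow(cells)), trialsPerCell), ]
        ord <- seq_len(nrow(runTrials))
        if (!is.null(seed))
            ord <- withSeed(childSeed(seed, r), sample(ord))
        runTrials <- runTrials[ord, ]
        enc <- as.integer(startTr)
        runTrials$run <- r
        runTrials$encode_tr <- NA_integer_
        runTrials$mgs_tr <- NA_integer_
        for (i in seq_len(nrow(runTrials))) {
            durTr <- as.integer(round((runTrials$presentation_s[i] +
                                       runTrials$delay_s[i]) / trSeconds))
            runTrials$encode_tr[i] <- enc
            runTrials$mgs_tr[i] <- enc + durTr
            enc <- runTrials$mgs_tr[i] + as.integer(itiTr)
        }
        eccIdx <- ((eccCounter + seq_len(nrow(runTrials)) - 1L) %% 3L) + 1L
        eccCounter <- eccCounter + nrow(runTrials)
        runTrials$eccentricity <- eccIdx
        runTrials$eccentricity_deg <- eccLevels[eccIdx]
        rows[[r]] <- runTrials
    }
    trials <- do.call(rbind, rows)
    rownames(trials) <- NULL
    nTrPerRun <- max(trials$mgs_tr) + 16L
    new("TaskDesign",
        trials = trials[, c("run", "presentation_s", "delay_s", "hemifield",
                            "eccentricity_deg", "eccentricity",
                            "encode_tr", "mgs_tr")],
        nRuns = as.integer(nRuns), nTrPerRun = as.integer(nTrPerRun),
        trSeconds = trSeconds)
}

#' Default ground-truth parameters for the gain-modulation generator
#'
#' The defaults describe a plausible adult session: trial gains with SD
#' 0.25 around their means, BOLD noise SD 1 against a pattern amplitude of
#' 20 (so single-state fluctuations account for a few percent of residual
#' whole-brain variance), reaction times near 500 ms coupled negatively to
#' the mean maintenance gain, and saccadic errors around 1 degree coupled
#' to the mean VME gain.
#'
#' @param gainSd numeric(6) per-component gain SD.
#' @param rtCoupling numeric(6) ms per unit gain deviation.
#' @param seCoupling numeric(6) degrees per unit gain deviation.
#' @param rtBaseMs baseline RT (ms).
#' @param rtNoiseSdMs residual RT SD (ms).
#' @param seNoiseSdDeg residual SE SD (degrees).
#' @param amplitude BOLD amplitude per unit gain (a.u.).
#' @param noiseSd i.i.d. BOLD noise SD (a.u.).
#' @param driftSd per-voxel Legendre drift coefficient SD (a.u.).
#' @param motionAmplitudeMm motion random-walk increment SD (mm).
#' @param motionArtifactScale BOLD a.u. per unit motion regressor.
#' @param pIncorrect probability a trial is unmeasurable.
#' @param timingJitter place the retrieval event at the trial's actual
#'   response time (TRUE by default), mixing latency-based coupling
#'   with the amplitude-based gain coupling as observed in real data.
#' @return a \linkS4class{GainGroundTruth}.
#' @export
gainGroundTruth <- function(gainSd = rep(0.25, 6),
                            rtCoupling = c(-50, 0, -100, 0, 0, 0),
                            seCoupling = c(0.3, 0, 0, 0, 0, 0),
                            rtBaseMs = 500, rtNoiseSdMs = 80,
                            seNoiseSdDeg = 0.8,
                            amplitude = 20, noiseSd = 1,
                            driftSd = 0.5, motionAmplitudeMm = 0.02,
                            motionArtifactScale = 0.5,
                            pIncorrect = 0.05, timingJitter = TRUE) {
    new("GainGroundTruth",
        gainSd = setNames(as.numeric(gainSd), .stateLabels),
        rtCoupling = setNames(as.numeric(rtCoupling), .stateLabels),
        seCoupling = setNames(as.numeric(seCoupling), .stateLabels),
        rtBaseMs = rtBaseMs, rtNoiseSdMs = rtNoiseSdMs,
        seNoiseSdDeg = seNoiseSdDeg, amplitude = amplitude,
        noiseSd = noiseSd, driftSd = driftSd,
        motionAmplitudeMm = motionAmplitudeMm,
        motionArtifactScale = motionArtifactScale,
        pIncorrect = pIncorrect, timingJitter = timingJitter)
}
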