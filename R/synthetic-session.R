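#' Generate one synthetic gain-modulated task fMRI session
#'
#' Builds a BOLD series from the linear gain-modulation model: each state
#' component's ground-truth pattern is expressed with an HRF time course
#' whose per-trial amplitude is a gain drawn around its mean (1 for mean
#' components, the target hemifield sign for spatial components). The VME
#' component is driven by an impulse at the encoding-saccade TR, retrieval
#' by an impulse at the MGS TR, and maintenance by delay-spanning
#' activity with an onset transient that decays linearly (3:1) toward
#' the saccade, so long and short delays produce sustained versus
#' transient maintenance expression and the delay activity's influence
#' on the MGS window peaks shortly after the saccade, as observed. Legendre drift, motion-locked
#' artifacts and i.i.d. Gaussian noise are added on top. Reaction time and
#' saccadic error are linear in the gain deviations plus noise.
#'
#' @param design a \linkS4class{TaskDesign}.
#' @param truth a \linkS4class{GainGroundTruth}.
#' @param patterns a ground-truth \linkS4class{BrainStateSet} (see
#'   \code{\link{generateStatePatterns}}).
#' @param seed integer seed; all draws derive from one stream.
#' @param maintOnsetLagTr TRs between the end of target presentation and
#'   the onset of delay-period (maintenance) activity, modelling the
#'   ramp-up of sustained activity after the visuomotor transient. The
#'   onset is never earlier than 4 TRs (one hemodynamic lag) after the
#'   encoding saccade -- so delay activity contributes exactly zero to
#'   the volume the VME pattern is extracted from -- and the boxcar
#'   always retains at least the TR before the MGS.
#' @return a list with elements \code{series} (\linkS4class{VolumeSeries},
#'   runs concatenated), \code{trials} (data.frame with run-local and
#'   global event TRs, rt_ms, se_deg, correct), \code{motion}
#'   (\linkS4class{MotionSeries}), \code{gains} (trials x 6 matrix of
#'   realized gains) and \code{truth}.
#' @examples
#' pat <- generateStatePatterns(50, seed = 1)
#' ses <- generateSession(mgsTaskDesign(), gainGroundTruth(), pat, seed = 2)
#' @export
generateSession <- function(design, truth, patterns, seed = NULL,
                            maintOnsetLagTr = 2L) {
    stopifnot(is(design, "TaskDesign"), is(truth, "GainGroundTruth"),
              is(patterns, "BrainStateSet"))
    withSeed(seed, .generateSessionImpl(design, truth, patterns,
                                        maintOnsetLagTr))
}

.generateSessionImpl <- function(design, truth, patterns,
                                 maintOnsetLagTr = 2L) {
    mask <- patterns@mask
    nv <- nVoxels(mask)
    tr <- design@trSeconds
    nTr <- design@nTrPerRun
    nRuns <- design@nRuns
    trials <- design@trials
    nTrial <- nrow(trials)
    trials$encode_tr_global <- trials$encode_tr +
        (trials$run - 1L) * nTr
    trials$mgs_tr_global <- trials$mgs_tr + (trials$run - 1L) * nTr

    ## realized gains: mean components fluctuate around 1, spatial
    ## components around the hemifield sign
    gainMean <- matrix(1, nTrial, 6, dimnames = list(NULL, .stateLabels))
    gainMean[, c(2, 4, 6)] <- trials$hemifield
    gains <- gainMean + matrix(rnorm(nTrial * 6), nTrial, 6) %*%
        diag(truth@gainSd)
    dimnames(gains) <- list(NULL, .stateLabels)

    ## HRF support is 15 TRs (21 s at TR 1.5), by which time the
    ## response has decayed to ~3% of peak; this keeps every event's
    ## response inside the duration + 15 TR FIR modelling window
    ## behavior first: the timing-jitter component places the retrieval
    ## event at the trial's actual response time
    dev <- gains - gainMean
    trials$rt_ms <- truth@rtBaseMs + as.numeric(dev %*% truth@rtCoupling) +
        rnorm(nTrial, 0, truth@rtNoiseSdMs)
    trials$se_deg <- as.numeric(dev %*% truth@seCoupling) +
        rnorm(nTrial, 0, truth@seNoiseSdDeg)
    trials$correct <- runif(nTrial) >= truth@pIncorrect

    kernel <- hrfKernel(tr, duration = 14 * tr)
    ## per-component event amplitude series (TRs x 6), runs concatenated
    events <- matrix(0, nRuns * nTr, 6,
                     dimnames = list(NULL, .stateLabels))
    presTr <- as.integer(round(trials$presentation_s / tr))
    jitter <- isTRUE(truth@timingJitter)
    for (i in seq_len(nTrial)) {
        enc <- trials$encode_tr_global[i]
        mgs <- trials$mgs_tr_global[i]
        delayTrs <- seq.int(min(max(enc + presTr[i] + maintOnsetLagTr,
                                    enc + 4L), mgs - 1L), mgs - 1L)
        ## onset-transient delay activity, decaying 3:1 across the delay
        delayW <- if (length(delayTrs) == 1L) 1 else
            seq(3, 1, length.out = length(delayTrs))
        for (s in if (jitter) 1:2 else 1:3) {
            cm <- 2L * s - 1L; cs <- 2L * s
            at <- switch(s, enc, delayTrs, mgs)
            w <- if (s == 2L) delayW else 1
            events[at, cm] <- events[at, cm] + gains[i, cm] * w
            events[at, cs] <- events[at, cs] + gains[i, cs] * w
        }
    }
    ## convolve within runs so the HRF never leaks across run boundaries
    expr <- matrix(0, nRuns * nTr, 6)
    for (r in seq_len(nRuns)) {
        rows <- (r - 1L) * nTr + seq_len(nTr)
        for (cc in 1:6)
            expr[rows, cc] <- convolveEvents(events[rows, cc], kernel)
    }
    if (jitter) {
        ## retrieval expressed at the response time: HRF sampled
        ## continuously at the MGS TR plus the trial's RT deviation
        for (i in seq_len(nTrial)) {
            mgs <- trials$mgs_tr_global[i]
            run <- trials$run[i]
            shiftS <- if (is.finite(trials$rt_ms[i]))
                (trials$rt_ms[i] - truth@rtBaseMs) / 1000 else 0
            hi <- min(run * nTr, mgs + 15L)
            at <- mgs:hi
            tRel <- (at - mgs) * tr - shiftS
            hv <- numeric(length(tRel))
            ok <- tRel >= 0 & tRel <= 14 * tr
            hv[ok] <- canonicalHrf(tRel[ok])
            expr[at, 5] <- expr[at, 5] + gains[i, "retr_mean"] * hv
            expr[at, 6] <- expr[at, 6] + gains[i, "retr_spatial"] * hv
        }
    }
    bold <- truth@amplitude * (patterns@patterns %*% t(expr))

    ## Legendre drift with independent per-voxel coefficients, per run
    if (truth@driftSd > 0) {
        L <- legendreDrift(nTr, 3)
        for (r in seq_len(nRuns)) {
            cols <- (r - 1L) * nTr + seq_len(nTr)
            coefs <- matrix(rnorm(nv * ncol(L), 0, truth@driftSd),
                            nv, ncol(L))
            bold[, cols] <- bold[, cols] + coefs %*% t(L)
        }
    }

    ## motion: per-run random walks in the six rigid parameters
    params <- matrix(0, nRuns * nTr, 6,
                     dimnames = list(NULL, c("trans_x", "trans_y",
                                             "trans_z", "rot_x", "rot_y",
                                             "rot_z")))
    if (truth@motionAmplitudeMm > 0)
        for (r in seq_len(nRuns)) {
            rows <- (r - 1L) * nTr + seq_len(nTr)
            params[rows, ] <- apply(matrix(
                rnorm(nTr * 6, 0, truth@motionAmplitudeMm), nTr, 6),
                2, cumsum)
        }
    fd <- framewiseDisplacement(params)
    motion <- new("MotionSeries", params = params,
                  totalDisplacement = fd$fd)

    ## motion-locked spatial artifacts: one random pattern per regressor
    if (truth@motionArtifactScale > 0 && truth@motionAmplitudeMm > 0) {
        regs <- cbind(params, fd$fd)
        artPat <- matrix(rnorm(nv * 7) / sqrt(nv), nv, 7)
        bold <- bold + truth@motionArtifactScale * (artPat %*% t(regs))
    }

    bold <- bold + matrix(rnorm(length(bold), 0, truth@noiseSd),
                          nrow(bold), ncol(bold))

    trials$rt_ms[!trials$correct] <- NA_real_
    trials$se_deg[!trials$correct] <- NA_real_

    list(series = new("VolumeSeries", data = bold, mask = mask,
                      trSeconds = tr),
         trials = trials, motion = motion, gains = gains, truth = truth)
}

#' Generate a synthetic developmental cohort
#'
#' Emulates an accelerated longitudinal design: subject ages are uniform
#' over \code{ageRange}, each subject contributes
#' \code{sessionsPerSubject} sessions spaced \code{sessionGapYears} apart,
#' and the injected per-component gain SD follows a linear age trend plus
#' subject-level noise. All subjects share one set of ground-truth state
#' patterns (one "brain").
#'
#' @param nSubjects number of subjects (>= 2).
#' @param ageRange numeric(2) age range in years at the first session.
#' @param gainSdIntercept numeric(6), gain SD at age 8.
#' @param gainSdSlope numeric(6), change in gain SD per year of age; must
#'   be finite.
#' @param subjectSd SD of the subject-level gain SD offset.
#' @param sessionsPerSubject sessions per subject.
#' @param sessionGapYears years between successive sessions.
#' @param design a \linkS4class{TaskDesign} shared by all sessions.
#' @param truth a \linkS4class{GainGroundTruth} template; its
#'   \code{gainSd} is overridden per session by the age model.
#' @param nVoxelsPerHemisphere voxels per hemisphere of the shared mask.
#' @param smoothness pattern smoothness (voxels).
#' @param seed integer seed.
#' @param processSession optional function applied to each session
#'   immediately after generation; its return value is stored in place
#'   of the raw session, so large BOLD series need not accumulate when
#'   the caller only keeps derived quantities.
#' @return a list with \code{sessions} (each a \code{generateSession}
#'   result plus \code{subject}, \code{age}, \code{visit}),
#'   \code{patterns} (shared ground truth \linkS4class{BrainStateSet}) and
#'   \code{table} (data.frame of subject, visit, age and the injected
#'   per-component gain SD).
#' @export
generateCohort <- function(nSubjects, ageRange = c(8, 33),
                           gainSdIntercept = rep(0.25, 6),
                           gainSdSlope = rep(0, 6),
                           subjectSd = 0.02,
                           sessionsPerSubject = 2,
                           sessionGapYears = 1.5,
                           design = mgsTaskDesign(),
                           truth = gainGroundTruth(),
                           nVoxelsPerHemisphere = 250,
                           smoothness = 5, seed = NULL,
                           processSession = NULL) {
    stopifnot(nSubjects >= 2)
    if (!all(is.finite(gainSdSlope)) || !all(is.finite(gainSdIntercept)))
        stop("gain SD age model must be finite")
    patterns <- generateStatePatterns(nVoxelsPerHemisphere, smoothness,
                                      seed = childSeed(seed, 0))
    ages <- withSeed(childSeed(seed, 1),
                     runif(nSubjects, ageRange[1], ageRange[2]))
    offsets <- withSeed(childSeed(seed, 2),
                        matrix(rnorm(nSubjects * 6, 0, subjectSd),
                               nSubjects, 6))
    sessions <- list()
    tab <- list()
    k <- 0L
    for (s in seq_len(nSubjects)) {
        for (v in seq_len(sessionsPerSubject)) {
            k <- k + 1L
            age <- ages[s] + (v - 1) * sessionGapYears
            sdv <- pmax(0.01, gainSdIntercept +
                              gainSdSlope * (age - 8) + offsets[s, ])
            tt <- truth
            tt@gainSd <- setNames(sdv, .stateLabels)
            ses <- generateSession(design, tt, patterns,
                                   seed = childSeed(seed, 100 + k))
            ses$subject <- s
            ses$age <- age
            ses$visit <- v
            sessions[[k]] <- if (is.null(processSession)) ses else
                processSession(ses)
            tab[[k]] <- data.frame(subject = s, visit = v, age = age,
                                   t(setNames(sdv, .stateLabels)))
        }
    }
    list(sessions = sessions, patterns = patterns,
         table = do.call(rbind, tab))
}
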