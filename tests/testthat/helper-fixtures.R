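## Shared fixtures, built once per test run. Sizes are kept small; the
## acceptance tests build their own larger cohorts.

fixSeed <- 20260929L

smallPatterns <- generateStatePatterns(100, smoothness = 3,
                                       seed = fixSeed)
smallMask <- brainMask(smallPatterns)

smallDesign <- mgsTaskDesign()

quietTruth <- gainGroundTruth(pIncorrect = 0)

smallSession <- generateSession(smallDesign, quietTruth, smallPatterns,
                                seed = fixSeed + 1)

## deterministic "noise-free" truth: no gain variability, no drift,
## no motion, tiny noise (noiseSd must be positive by contract)
silentTruth <- gainGroundTruth(gainSd = rep(0, 6), noiseSd = 1e-8,
                               driftSd = 0, motionAmplitudeMm = 0,
                               motionArtifactScale = 0, pIncorrect = 0,
                               rtNoiseSdMs = 1e-6, seNoiseSdDeg = 1e-6,
                               timingJitter = FALSE)

## brute-force saccade detector used as the independent oracle: naive
## linear scans, no vectorization shared with the implementation
oracleDetectSaccades <- function(v, minPeakVel = 30) {
    n <- length(v)
    events <- list()
    lastEnd <- 0
    i <- 2
    while (i <= n - 1) {
        if (v[i] > v[i - 1] && v[i] >= v[i + 1] &&
            v[i] >= minPeakVel && i > lastEnd) {
            thr <- v[i] / 10
            s <- 1
            for (j in (i - 1):1) if (v[j] < thr) { s <- j; break }
            e <- n
            for (j in (i + 1):n) if (v[j] < thr) { e <- j; break }
            events[[length(events) + 1]] <-
                c(start = s, peak = i, end = e)
            lastEnd <- e
        }
        i <- i + 1
    }
    if (!length(events))
        return(data.frame(start = integer(0), peak = integer(0),
                          end = integer(0)))
    as.data.frame(do.call(rbind, events))
}

## random synthetic velocity trace with a few embedded pulses
randomVelocityTrace <- function(n = 300) {
    v <- abs(rnorm(n, 0, 3))
    nPulse <- sample(0:3, 1)
    for (k in seq_len(nPulse)) {
        at <- sample(20:(n - 20), 1)
        width <- sample(3:8, 1)
        peak <- runif(1, 40, 400)
        shape <- peak * exp(-0.5 * ((-width:width) / (width / 2))^2)
        v[at + (-width:width)] <- pmax(v[at + (-width:width)], shape)
    }
    v
}
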