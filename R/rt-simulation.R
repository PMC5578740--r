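#' Default reaction-time distribution for mechanism simulations
#'
#' Log-normal reaction times matched to plausible memory-guided saccade
#' latencies (median about 450 ms, coefficient of variation about 25
#' percent). Any empirical RT vector, for example the cohort generator's
#' reaction times, can be passed to \code{\link{simulateMechanism}}
#' instead.
#'
#' @param n number of draws.
#' @return numeric RTs in ms.
#' @export
defaultRtDistribution <- function(n) {
    rlnorm(n, meanlog = log(450), sdlog = 0.25)
}

#' Simulate timing-, amplitude- or mixed-mechanism HRF residuals
#'
#' Each trial is an impulse on a 60 ms grid convolved with the canonical
#' HRF. Under the timing mechanism the unit impulse sits at the trial's
#' RT bin; under the amplitude mechanism the impulse sits at the mean-RT
#' bin for every trial with height 1 plus a linearly interpolated
#' modulation in [-ampModMax, +ampModMax] (+ for the fastest RT, - for
#' the slowest); the mixed mechanism applies the RT-bin placement and
#' the modulation together. The cross-trial mean series is subtracted,
#' trials are split into fast and slow halves at the median RT, and the
#' mean residual series and their cumulative time integrals are
#' returned.
#'
#' @param mode "timing", "amplitude" or "mixed".
#' @param rtMs reaction times in ms, or NULL to draw
#'   \code{\link{defaultRtDistribution}} samples.
#' @param nTrials number of trials (400).
#' @param binSeconds time bin (0.060 s).
#' @param ampModMax maximum amplitude modulation (0.25).
#' @param seed integer seed (used when rtMs is NULL).
#' @return a \linkS4class{MechanismSim}.
#' @examples
#' sim <- simulateMechanism("timing", seed = 1)
#' @export
simulateMechanism <- function(mode = c("timing", "amplitude", "mixed"),
                              rtMs = NULL, nTrials = 400,
                              binSeconds = 0.060, ampModMax = 0.25,
                              seed = NULL) {
    mode <- match.arg(mode)
    if (is.null(rtMs))
        rtMs <- withSeed(seed, defaultRtDistribution(nTrials))
    if (any(rtMs <= 0)) stop("reaction times must be strictly positive")
    nTrials <- length(rtMs)
    binMs <- binSeconds * 1000
    rtBin <- pmax(1L, as.integer(round(rtMs / binMs)) + 1L)
    meanBin <- pmax(1L, as.integer(round(mean(rtMs) / binMs)) + 1L)
    kernel <- canonicalHrf(seq(0, 30, by = binSeconds))
    nBin <- max(rtBin, meanBin) + length(kernel)
    ## linear modulation: +ampModMax at the fastest RT, -ampModMax at
    ## the slowest
    spread <- max(rtMs) - min(rtMs)
    mod <- if (spread == 0) rep(0, nTrials) else
        ampModMax - 2 * ampModMax * (rtMs - min(rtMs)) / spread
    series <- matrix(0, nTrials, nBin)
    for (i in seq_len(nTrials)) {
        idx <- switch(mode, timing = rtBin[i], amplitude = meanBin,
                      mixed = rtBin[i])
        h <- switch(mode, timing = 1, amplitude = 1 + mod[i],
                    mixed = 1 + mod[i])
        cols <- idx:(idx + length(kernel) - 1L)
        series[i, cols] <- series[i, cols] + h * kernel
    }
    meanSeries <- colMeans(series)
    resid <- sweep(series, 2, meanSeries)
    fast <- rtMs <= median(rtMs)
    if (sum(fast) == nTrials) fast <- rank(rtMs, ties.method = "first") <=
        nTrials / 2
    residFast <- colMeans(resid[fast, , drop = FALSE])
    residSlow <- colMeans(resid[!fast, , drop = FALSE])
    new("MechanismSim", mode = mode, rtMs = rtMs,
        binSeconds = binSeconds, meanSeries = meanSeries,
        residFast = residFast, residSlow = residSlow,
        integralFast = cumsum(residFast) * binSeconds,
        integralSlow = cumsum(residSlow) * binSeconds)
}

## Closed-form amplitude-mode oracle: the terminal integral of the
## fast-half mean residual equals the mean fast-half modulation times the
## HRF time integral.
amplitudeOracleMagnitude <- function(rtMs, binSeconds = 0.060,
                                     ampModMax = 0.25) {
    spread <- max(rtMs) - min(rtMs)
    if (spread == 0) return(0)
    mod <- ampModMax - 2 * ampModMax * (rtMs - min(rtMs)) / spread
    fast <- rtMs <= median(rtMs)
    if (all(fast)) fast <- rank(rtMs, ties.method = "first") <=
        length(rtMs) / 2
    hrfInt <- sum(canonicalHrf(seq(0, 30, by = binSeconds))) *
        binSeconds
    abs((mean(mod[fast]) - mean(mod)) * hrfInt)
}

#' Classify a mechanism simulation from its integral signature
#'
#' Decision rule on the cumulative integrals of the fast- and slow-half
#' mean residual series. Both terminal integrals near zero (below 5
#' percent of the closed-form amplitude-mode magnitude for the same RTs)
#' indicate a pure timing mechanism. Opposite-signed non-zero terminals
#' indicate amplitude involvement; whether the fast/slow integral
#' difference retains most of its peak value separates a pure amplitude
#' mechanism (no re-convergence; the retained fraction matches the HRF's
#' terminal-to-peak cumulative ratio) from a mixed mechanism (early
#' bifurcation followed by partial re-convergence). Degenerate inputs
#' yield "indeterminate".
#'
#' @details A pure amplitude mechanism makes the fast-minus-slow integral
#' difference exactly proportional to the cumulative HRF anchored at the
#' mean-RT bin (closed form); a timing admixture adds an early bifurcation
#' that later re-converges, deforming that shape. The classifier therefore
#' measures the relative least-squares misfit of the observed difference
#' curve to the amplitude-mode shape.
#'
#' @param sim a \linkS4class{MechanismSim}.
#' @param zeroFrac terminal-integral fraction of the amplitude oracle
#'   below which a terminal counts as zero (0.05).
#' @param shapeTol relative misfit to the amplitude-mode shape above
#'   which re-convergence is declared (0.05).
#' @return character: "timing", "amplitude", "mixed" or
#'   "indeterminate".
#' @export
integralSignature <- function(sim, zeroFrac = 0.05, shapeTol = 0.05) {
    tF <- sim@integralFast[length(sim@integralFast)]
    tS <- sim@integralSlow[length(sim@integralSlow)]
    M <- amplitudeOracleMagnitude(sim@rtMs, sim@binSeconds)
    if (M == 0 || max(abs(sim@residFast), abs(sim@residSlow)) == 0)
        return("indeterminate")
    if (max(abs(tF), abs(tS)) < zeroFrac * M) return("timing")
    if (sign(tF) == sign(tS) || tF <= tS) return("indeterminate")
    dd <- sim@integralFast - sim@integralSlow
    ## closed-form amplitude-mode shape: cumulative HRF at the mean bin
    h <- canonicalHrf(seq(0, 30, by = sim@binSeconds))
    ref <- numeric(length(dd))
    meanBin <- max(1L, as.integer(round(mean(sim@rtMs) /
                                        (sim@binSeconds * 1000))) + 1L)
    upto <- min(length(dd), meanBin + length(h) - 1L)
    ref[meanBin:upto] <- cumsum(h)[seq_len(upto - meanBin + 1L)]
    if (upto < length(dd)) ref[(upto + 1L):length(dd)] <- sum(h)
    a <- sum(dd * ref) / sum(ref^2)
    misfit <- sqrt(sum((dd - a * ref)^2) / sum(dd^2))
    if (misfit <= shapeTol) "amplitude" else "mixed"
}

#' Empirical integral signature of measured fluctuation snippets
#'
#' Mirrors the simulation diagnostic on measured data: snippets of a
#' component's fluctuation time course beginning at the MGS TR are split
#' into fast and slow halves at the median RT, averaged, interpolated to
#' the 60 ms simulation grid by shape-preserving piecewise-cubic
#' interpolation, and integrated cumulatively.
#'
#' @param snippets trials x TRs matrix of fluctuation values, column 1
#'   at the MGS TR.
#' @param rtMs per-trial reaction times (ms).
#' @param trSeconds TR duration (s).
#' @param binSeconds target resolution (s).
#' @return list with residFast, residSlow, integralFast, integralSlow,
#'   timeS (the 60 ms grid).
#' @export
empiricalSignature <- function(snippets, rtMs, trSeconds = 1.5,
                               binSeconds = 0.060) {
    ok <- is.finite(rtMs) & apply(is.finite(snippets), 1, all)
    snippets <- snippets[ok, , drop = FALSE]
    rtMs <- rtMs[ok]
    if (nrow(snippets) < 20)
        warning("fewer than 10 trials per half; signature is unstable")
    fast <- rtMs <= median(rtMs)
    tIn <- (seq_len(ncol(snippets)) - 1L) * trSeconds
    tOut <- seq(0, max(tIn), by = binSeconds)
    interp <- function(y) {
        if (isTRUE(all.equal(trSeconds, binSeconds))) return(y)
        pracma::pchip(tIn, y, tOut)
    }
    mf <- interp(colMeans(snippets[fast, , drop = FALSE]))
    ms <- interp(colMeans(snippets[!fast, , drop = FALSE]))
    list(residFast = mf, residSlow = ms,
         integralFast = cumsum(mf) * binSeconds,
         integralSlow = cumsum(ms) * binSeconds, timeS = tOut)
}
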