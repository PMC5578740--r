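#' Detect saccades in an eye-velocity trace
#'
#' Candidate events are local maxima of the velocity trace above an
#' absolute floor. For each candidate (taken in temporal order, skipping
#' candidates inside an already-detected event), the start and end are the
#' nearest samples before and after the peak where velocity drops below
#' one tenth of the peak velocity; events never overlap.
#'
#' @param velocity numeric velocity trace (degrees/s), finite.
#' @param sampleRateHz sampling rate (60 Hz for the MGS task).
#' @param minPeakVel absolute floor on peak velocity (degrees/s).
#' @return data.frame with columns start, peak, end (sample indices) and
#'   peakVelocity; zero rows when no saccade is found.
#' @export
detectSaccades <- function(velocity, sampleRateHz = 60,
                           minPeakVel = 30) {
    stopifnot(all(is.finite(velocity)))
    n <- length(velocity)
    empty <- data.frame(start = integer(0), peak = integer(0),
                        end = integer(0), peakVelocity = numeric(0))
    if (n < 3) return(empty)
    v <- velocity
    isPeak <- which(v[2:(n - 1)] > v[1:(n - 2)] &
                    v[2:(n - 1)] >= v[3:n] &
                    v[2:(n - 1)] >= minPeakVel) + 1L
    if (!length(isPeak)) return(empty)
    out <- list()
    lastEnd <- 0L
    for (p in isPeak) {
        if (p <= lastEnd) next
        thr <- v[p] / 10
        below <- which(v[seq_len(p - 1)] < thr)
        s <- if (length(below)) max(below) else 1L
        after <- which(v[(p + 1):n] < thr)
        e <- if (length(after)) p + min(after) else n
        out[[length(out) + 1L]] <-
            data.frame(start = s, peak = p, end = e, peakVelocity = v[p])
        lastEnd <- e
    }
    do.call(rbind, out)
}

#' Score trials from detected saccades
#'
#' Assigns to each trial its visually guided saccade (the first event
#' starting between target onset and fixation offset) and its memory
#' guided saccade (the first event starting at or after fixation offset,
#' within the response window). Reaction time is the interval from
#' fixation offset to MGS start; saccadic error is the signed difference
#' between the gaze position at the MGS end and the target location.
#' Trials lacking either measurable saccade are marked incorrect. The
#' session is flagged for exclusion when fewer than half the trials of
#' any of the four task conditions are measurable.
#'
#' @param events saccade events from \code{\link{detectSaccades}}.
#' @param trials data.frame with columns target_onset_sample,
#'   fixation_offset_sample, response_end_sample, target_deg,
#'   presentation_s, delay_s.
#' @param position numeric gaze-position trace (degrees), same sampling
#'   as the velocity trace.
#' @param sampleRateHz sampling rate (Hz).
#' @return the trials data.frame with added rt_ms, se_deg and correct
#'   columns and an \code{excludeSession} attribute (logical).
#' @export
scoreTrials <- function(events, trials, position, sampleRateHz = 60) {
    trials$rt_ms <- NA_real_
    trials$se_deg <- NA_real_
    trials$correct <- FALSE
    for (i in seq_len(nrow(trials))) {
        on <- trials$target_onset_sample[i]
        off <- trials$fixation_offset_sample[i]
        lim <- trials$response_end_sample[i]
        vgs <- which(events$start >= on & events$start < off)
        mgs <- which(events$start >= off & events$start <= lim)
        if (length(vgs) && length(mgs)) {
            m <- events[mgs[1], ]
            trials$rt_ms[i] <- (m$start - off) / sampleRateHz * 1000
            trials$se_deg[i] <- position[m$end] - trials$target_deg[i]
            trials$correct[i] <- TRUE
        }
    }
    cellRate <- tapply(trials$correct,
                       interaction(trials$presentation_s,
                                   trials$delay_s), mean)
    attr(trials, "excludeSession") <- any(cellRate < 0.5, na.rm = TRUE)
    trials
}

#' Session-level behavioral summaries
#'
#' Per task condition: mean and SD of reaction time over correct trials,
#' saccade inaccuracy (absolute value of the mean signed error, computed
#' per target then averaged) and imprecision (SD of the signed error per
#' target, averaged). Conditions with fewer than 2 correct trials yield
#' NA rather than an error.
#'
#' @param trials a scored trial data.frame with presentation_s, delay_s,
#'   hemifield, eccentricity_deg, rt_ms, se_deg, correct.
#' @return data.frame with one row per condition: presentation_s,
#'   delay_s, meanRt, sdRt, inaccuracy, imprecision, nCorrect.
#' @export
behavioralSummaries <- function(trials) {
    tr <- trials[trials$correct & is.finite(trials$rt_ms), ]
    conds <- unique(trials[, c("presentation_s", "delay_s")])
    conds <- conds[order(conds$presentation_s, conds$delay_s), ]
    out <- list()
    for (i in seq_len(nrow(conds))) {
        cc <- tr[tr$presentation_s == conds$presentation_s[i] &
                 tr$delay_s == conds$delay_s[i], ]
        row <- data.frame(presentation_s = conds$presentation_s[i],
                          delay_s = conds$delay_s[i],
                          meanRt = NA_real_, sdRt = NA_real_,
                          inaccuracy = NA_real_, imprecision = NA_real_,
                          nCorrect = nrow(cc))
        if (nrow(cc) >= 2) {
            row$meanRt <- mean(cc$rt_ms)
            row$sdRt <- sd(cc$rt_ms)
            tgt <- interaction(cc$hemifield, cc$eccentricity_deg,
                               drop = TRUE)
            row$inaccuracy <- mean(abs(tapply(cc$se_deg, tgt, mean)))
            imp <- tapply(cc$se_deg, tgt, sd)
            row$imprecision <- mean(imp, na.rm = TRUE)
        }
        out[[i]] <- row
    }
    do.call(rbind, out)
}

#' Extract MGS-aligned snippets of brain-state fluctuation
#'
#' Cuts the z-scored fluctuation time course of each state component into
#' windows of +/- \code{halfWidth} TRs centered on each trial's MGS TR
#' (relative TR 0). Cells falling outside the trial's run are NA and are
#' excluded from later fits.
#'
#' @param fluct an \linkS4class{ExpressionSeries} of residual
#'   fluctuations (typically z-scored).
#' @param trials trial data.frame with mgs_tr_global and run columns.
#' @param nTrPerRun TRs per run (defines run boundaries in the
#'   concatenated series).
#' @param halfWidth window half width in TRs (15).
#' @return a \linkS4class{SnippetStack}.
#' @export
extractSnippets <- function(fluct, trials, nTrPerRun, halfWidth = 15) {
    W <- fluct@weights[seq_len(6), , drop = FALSE]
    hw <- as.integer(halfWidth)
    nTrial <- nrow(trials)
    vals <- array(NA_real_, dim = c(nTrial, 2L * hw + 1L, 6L),
                  dimnames = list(NULL, as.character(-hw:hw),
                                  .stateLabels))
    for (i in seq_len(nTrial)) {
        center <- trials$mgs_tr_global[i]
        lo <- (trials$run[i] - 1L) * nTrPerRun + 1L
        hi <- trials$run[i] * nTrPerRun
        rel <- -hw:hw
        at <- center + rel
        ok <- at >= lo & at <= hi & at <= ncol(W)
        vals[i, which(ok), ] <- t(W[, at[ok], drop = FALSE])
    }
    new("SnippetStack", values = vals, trials = trials,
        halfWidth = hw)
}

#' Combine snippet stacks across sessions
#'
#' Row-binds the trials and values of several \linkS4class{SnippetStack}
#' objects (which must share half width and component labels) so
#' trial-wise models can pool sessions and subjects.
#'
#' @param stacks a list of \linkS4class{SnippetStack} objects.
#' @return a single \linkS4class{SnippetStack}.
#' @export
bindSnippetStacks <- function(stacks) {
    stopifnot(length(stacks) >= 1)
    hw <- stacks[[1]]@halfWidth
    for (s in stacks) stopifnot(s@halfWidth == hw)
    nRows <- vapply(stacks, function(s) dim(s@values)[1], numeric(1))
    vals <- array(NA_real_, c(sum(nRows), 2L * hw + 1L, 6L),
                  dimnames = dimnames(stacks[[1]]@values))
    at <- 0L
    for (s in stacks) {
        vals[at + seq_len(dim(s@values)[1]), , ] <- s@values
        at <- at + dim(s@values)[1]
    }
    trials <- do.call(rbind, lapply(stacks, slot, "trials"))
    rownames(trials) <- NULL
    new("SnippetStack", values = vals, trials = trials, halfWidth = hw)
}

## ---- exact profiled-ML engine for the random-intercept LMM ----------
## Profiled deviance of y ~ X beta + b_group, b ~ N(0, theta^2 sigma^2).
## V = sigma^2 (I + theta^2 Z Z') is block diagonal by group, so the
## GLS whitening is closed-form per group and the ML deviance can be
## profiled down to a 1-D optimization in theta. Used to make the
## parametric-bootstrap likelihood-ratio test affordable; agrees with
## lme4's ML deviance (tested).
lmmRanIntFit <- function(X, y, group, thetaMax = 25) {
    g <- as.integer(group)
    m <- tabulate(g)
    n <- length(y)
    Xbar <- rowsum(X, g) / m
    ybar <- rowsum(y, g)[, 1] / m
    XbarE <- Xbar[g, , drop = FALSE]
    ybarE <- ybar[g]
    devAt <- function(theta) {
        cg <- (1 - 1 / sqrt(1 + theta^2 * m))[g]
        fit <- .lm.fit(X - cg * XbarE, y - cg * ybarE)
        rss <- sum(fit$residuals^2)
        list(dev = n * log(2 * pi * rss / n) +
                 sum(log(1 + theta^2 * m)) + n,
             fit = fit, rss = rss)
    }
    if (max(m) == n && length(m) == 1) {
        opt <- list(minimum = 0)        # single group: plain OLS
    } else {
        opt <- optimize(function(th) devAt(th)$dev, c(0, thetaMax),
                        tol = 1e-6)
    }
    ## the optimum can sit at the boundary theta = 0
    d0 <- devAt(0)
    dOpt <- devAt(opt$minimum)
    if (d0$dev <= dOpt$dev) { opt$minimum <- 0; dOpt <- d0 }
    sigma <- sqrt(dOpt$rss / n)
    ## .lm.fit returns coefficients in pivoted column order
    beta <- numeric(ncol(X))
    r <- dOpt$fit$rank
    beta[dOpt$fit$pivot[seq_len(r)]] <- dOpt$fit$coefficients[seq_len(r)]
    list(dev = dOpt$dev, logLik = -dOpt$dev / 2, beta = beta,
         sigma = sigma, theta = opt$minimum, group = g, m = m)
}

## Simulated (parametric bootstrap) likelihood-ratio test of nested
## fixed-effect structures sharing the random-intercept term: simulate
## from the fitted null, refit both models per draw, and compare the
## observed LRT statistic with the simulated distribution.
simulatedLrt <- function(X0, X1, y, group, nSim = 5000, seed = NULL) {
    f0 <- lmmRanIntFit(X0, y, group)
    f1 <- lmmRanIntFit(X1, y, group)
    stat <- f0$dev - f1$dev
    if (nSim < 1)
        return(list(stat = stat, p = NA_real_, null = f0, full = f1))
    g <- f0$group
    nG <- length(f0$m)
    mu <- drop(X0 %*% f0$beta)
    sigB <- f0$theta * f0$sigma
    sims <- withSeed(seed, {
        out <- numeric(nSim)
        for (i in seq_len(nSim)) {
            ystar <- mu + sigB * rnorm(nG)[g] +
                rnorm(length(y), 0, f0$sigma)
            out[i] <- lmmRanIntFit(X0, ystar, g)$dev -
                lmmRanIntFit(X1, ystar, g)$dev
        }
        out
    })
    p <- (1 + sum(sims >= stat)) / (nSim + 1)
    list(stat = stat, p = p, null = f0, full = f1, sims = sims)
}

## z-score within session x condition cells (the four presentation x
## delay conditions), the convention for trial-wise behavior.
zscoreWithinCells <- function(x, trials) {
    cell <- interaction(trials$session, trials$presentation_s,
                        trials$delay_s, drop = TRUE)
    out <- numeric(length(x))
    for (l in levels(cell)) {
        idx <- which(cell == l)
        out[idx] <- zscore(x[idx])
    }
    out
}

#' Trial-wise regression of behavior on brain-state fluctuation
#'
#' At a relative TR of the MGS-aligned snippets, fits a null model of
#' trial behavior (run, hemifield, eccentricity and its square, the
#' other behavioral measure and its square, random subject intercept)
#' and a full model adding the three mean-state fluctuation terms and
#' the three spatial-state-by-hemifield interactions. Reports the
#' difference in ordinary R-squared, the full-model state coefficients,
#' and a simulated likelihood-ratio p value obtained by parametric
#' bootstrap of the null model (both models refit per draw).
#'
#' Reaction time and saccadic error are z-scored within session by task
#' condition; as a response, SE is additionally rectified (absolute
#' value of the z-score) so large values mean large error.
#'
#' @param stack a \linkS4class{SnippetStack} whose trials carry subject,
#'   session, run, hemifield, eccentricity, rt_ms, se_deg, correct.
#' @param behavior "rt" or "se": which measure is the response.
#' @param relTr relative TR (within +/- halfWidth) of the state terms.
#' @param nSim bootstrap draws for the simulated LRT (0 skips the test;
#'   values below 100 warn).
#' @param seed integer seed for the bootstrap.
#' @return list with relTr, nTrials, deltaR2, r2Full, r2Null, lrtStat,
#'   p, and coefTable (the six state-term estimates with SEs, t and
#'   normal-approximation p values).
#' @export
trialwiseRegression <- function(stack, behavior = c("rt", "se"), relTr,
                                nSim = 5000, seed = NULL) {
    behavior <- match.arg(behavior)
    if (nSim > 0 && nSim < 100)
        warning("nSim below 100 gives a very coarse simulated-LRT p")
    tr <- stack@trials
    hw <- stack@halfWidth
    stopifnot(abs(relTr) <= hw)
    if (!all(is.finite(tr$rt_ms[tr$correct])) ||
        !all(is.finite(tr$se_deg[tr$correct])))
        stop("correct trials must have finite behavior")
    rtZ <- zscoreWithinCells(tr$rt_ms, tr)
    seZ <- zscoreWithinCells(tr$se_deg, tr)
    S <- stack@values[, as.character(relTr), ]      # trials x 6
    keep <- tr$correct & apply(is.finite(S), 1, all) &
        is.finite(rtZ) & is.finite(seZ)
    d <- data.frame(y = if (behavior == "rt") rtZ[keep] else
                        abs(seZ[keep]),
                    other = if (behavior == "rt") seZ[keep] else
                        rtZ[keep],
                    run = tr$run[keep], hemi = tr$hemifield[keep],
                    ecc = tr$eccentricity[keep],
                    subject = factor(tr$subject[keep]))
    Sk <- S[keep, , drop = FALSE]
    X0 <- cbind(intercept = 1, run = d$run, hemi = d$hemi, ecc = d$ecc,
                ecc2 = d$ecc^2, other = d$other, other2 = d$other^2)
    X1 <- cbind(X0,
                vme_mean = Sk[, "vme_mean"],
                maint_mean = Sk[, "maint_mean"],
                retr_mean = Sk[, "retr_mean"],
                vme_spatial_x_hemi = Sk[, "vme_spatial"] * d$hemi,
                maint_spatial_x_hemi = Sk[, "maint_spatial"] * d$hemi,
                retr_spatial_x_hemi = Sk[, "retr_spatial"] * d$hemi)
    lrt <- simulatedLrt(X0, X1, d$y, d$subject, nSim = nSim,
                        seed = seed)
    r2 <- function(fit, X) {
        ## ordinary R2 from fitted values including the subject BLUPs
        g <- fit$group
        res <- d$y - drop(X %*% fit$beta)
        lam <- (fit$theta^2 * fit$m) / (1 + fit$theta^2 * fit$m)
        blup <- lam * (rowsum(res, g)[, 1] / fit$m)
        yhat <- drop(X %*% fit$beta) + blup[g]
        1 - sum((d$y - yhat)^2) / sum((d$y - mean(d$y))^2)
    }
    r2Null <- r2(lrt$null, X0)
    r2Full <- r2(lrt$full, X1)
    ## GLS covariance of the full-model coefficients
    fit1 <- lrt$full
    cg <- (1 - 1 / sqrt(1 + fit1$theta^2 * fit1$m))[fit1$group]
    Xw <- X1 - cg * (rowsum(X1, fit1$group) / fit1$m)[fit1$group, ]
    covB <- fit1$sigma^2 * chol2inv(chol(crossprod(Xw)))
    stateTerms <- colnames(X1)[8:13]
    est <- fit1$beta[8:13]
    se <- sqrt(diag(covB))[8:13]
    coefTable <- data.frame(term = stateTerms, estimate = est,
                            stdError = se, t = est / se,
                            p = 2 * pnorm(-abs(est / se)))
    list(relTr = relTr, nTrials = sum(keep),
         deltaR2 = r2Full - r2Null, r2Full = r2Full, r2Null = r2Null,
         lrtStat = lrt$stat, p = lrt$p, coefTable = coefTable)
}

#' Delta R-squared profile across relative TRs
#'
#' Runs \code{\link{trialwiseRegression}} without the bootstrap at every
#' relative TR of a snippet stack, for locating where the brain/behavior
#' relationship peaks before spending bootstrap draws there.
#'
#' @inheritParams trialwiseRegression
#' @param relTrs integer vector of relative TRs.
#' @return data.frame with relTr, nTrials, deltaR2, lrtStat.
#' @export
trialwiseProfile <- function(stack, behavior = c("rt", "se"),
                             relTrs = -15:15) {
    behavior <- match.arg(behavior)
    rows <- lapply(relTrs, function(k) {
        r <- trialwiseRegression(stack, behavior, k, nSim = 0)
        data.frame(relTr = k, nTrials = r$nTrials,
                   deltaR2 = r$deltaR2, lrtStat = r$lrtStat)
    })
    do.call(rbind, rows)
}

#' Quadratic speed-accuracy relationship
#'
#' Regresses saccadic error on z-scored reaction time and its square;
#' a positive quadratic coefficient means both unusually fast and
#' unusually slow responses are inaccurate.
#'
#' @param rtZ z-scored reaction times.
#' @param se saccadic error values (rectified by the caller if desired).
#' @return list with coefficient, stdError, t, p (for the quadratic
#'   term) and the lm fit.
#' @export
speedAccuracyQuadratic <- function(rtZ, se) {
    ok <- is.finite(rtZ) & is.finite(se)
    if (sum(ok) < 10) stop("need at least 10 trials")
    if (sd(rtZ[ok]) == 0 || sd(se[ok]) == 0)
        stop("degenerate variance in inputs")
    fit <- lm(se[ok] ~ rtZ[ok] + I(rtZ[ok]^2))
    cf <- summary(fit)$coefficients
    list(coefficient = cf[3, 1], stdError = cf[3, 2], t = cf[3, 3],
         p = cf[3, 4], fit = fit)
}
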