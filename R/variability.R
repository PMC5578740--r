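#' Variance decomposition of residual BOLD around the MGS
#'
#' Over the TRs in \code{window} around each correct memory-guided
#' saccade, the whole-brain residual at each TR is split into
#' state-attributable, motion-template, other-nuisance and unexplained
#' squared error by projecting it on a sequentially orthonormalized
#' design (nuisance templates first, then the six states in canonical
#' order). Because the attribution uses orthonormal basis columns, the
#' additivity SS_brain = SS_VME + SS_Maint + SS_Retrieval is exact.
#'
#' @param residuals a \linkS4class{ResidualSeries} (or
#'   \linkS4class{VolumeSeries}) of deconvolution residuals.
#' @param states a \linkS4class{BrainStateSet}.
#' @param nuisance a \linkS4class{NuisanceSet} or NULL.
#' @param mgsTrs integer global TRs of the correct MGS events.
#' @param window integer TR offsets around each MGS (0:5).
#' @return a \linkS4class{VarianceDecomposition}.
#' @export
decomposeVariance <- function(residuals, states, nuisance = NULL,
                              mgsTrs, window = 0:5) {
    if (length(mgsTrs) == 0) stop("no correct MGS events supplied")
    nT <- ncol(residuals@data)
    trs <- sort(unique(as.integer(outer(mgsTrs, window, "+"))))
    if (any(trs < 1 | trs > nT))
        stop("window TRs fall outside the series")
    Dn <- if (is.null(nuisance)) NULL else nuisance@templates
    nNuis <- if (is.null(Dn)) 0L else ncol(Dn)
    D <- cbind(Dn, states@patterns)
    qrD <- qr(D, tol = 1e-10)
    if (qrD$rank < ncol(D)) stop("projection design is rank deficient")
    Q <- qr.Q(qrD)
    Y <- residuals@data[, trs, drop = FALSE]
    proj <- crossprod(Q, Y)               # p x nTr coordinates
    ssCol <- rowSums(proj^2)
    stateCols <- nNuis + seq_len(6)
    labels <- c(if (nNuis) nuisance@labels, .stateLabels)
    ssMotion <- sum(ssCol[grepl("^motion_pc", labels)])
    ssOther <- sum(ssCol[seq_len(nNuis)]) - ssMotion
    ssError <- sum(Y^2) - sum(ssCol)
    new("VarianceDecomposition",
        ssVme = sum(ssCol[stateCols[1:2]]),
        ssMaint = sum(ssCol[stateCols[3:4]]),
        ssRetrieval = sum(ssCol[stateCols[5:6]]),
        ssMotion = ssMotion, ssNuisanceOther = ssOther,
        ssError = max(ssError, 0),
        window = as.integer(window), nTrUsed = length(trs))
}

#' Developmental trajectory of a session-level measure
#'
#' Mixed-effects fit of a per-session scalar on age (linear or inverse)
#' with optional covariates and a random subject intercept (plus a random
#' age slope when requested, for individual-slope extraction). Models are
#' fit by maximum likelihood so AIC comparisons across age forms are
#' valid. A singular or failed mixed fit falls back to fixed-effects OLS
#' with a warning.
#'
#' @param data data.frame with columns \code{y}, \code{age},
#'   \code{subject} and any covariates.
#' @param form "linear_age" or "inverse_age".
#' @param covariates character vector of covariate column names.
#' @param randomSlope if TRUE, include a per-subject random age term.
#' @return a \linkS4class{TrajectoryFit}.
#' @export
fitTrajectory <- function(data, form = c("linear_age", "inverse_age"),
                          covariates = character(0),
                          randomSlope = FALSE) {
    form <- match.arg(form)
    stopifnot(all(c("y", "age", "subject") %in% names(data)),
              all(covariates %in% names(data)))
    if (length(unique(data$subject)) < 2 || nrow(data) < 3)
        stop("need at least 2 subjects and 3 sessions")
    data$subject <- factor(data$subject)
    data$ageTerm <- if (form == "linear_age") data$age else 1 / data$age
    ## covariates are standardized (the age term is not), so their
    ## coefficients are per-SD and the fit is well scaled
    for (v in covariates) {
        s <- sd(data[[v]])
        if (is.finite(s) && s > 0)
            data[[v]] <- (data[[v]] - mean(data[[v]])) / s
    }
    fixedRhs <- paste(c("ageTerm", covariates), collapse = " + ")
    reTerm <- if (randomSlope) "(1 + ageTerm | subject)" else
        "(1 | subject)"
    fml <- as.formula(paste("y ~", fixedRhs, "+", reTerm))
    fit <- tryCatch(
        lme4::lmer(fml, data = data, REML = FALSE,
                   control = lme4::lmerControl(
                       check.conv.singular = "ignore")),
        error = function(e) NULL)
    if (is.null(fit)) {
        warning("mixed model failed; falling back to fixed-effects OLS")
        fit <- lm(as.formula(paste("y ~", fixedRhs)), data = data)
        fe <- coef(fit)
        ct <- summary(fit)$coefficients
        subjCoefs <- data.frame()
    } else {
        fe <- lme4::fixef(fit)
        ct <- summary(fit)$coefficients
        ct <- cbind(ct, `p value` = 2 * pnorm(-abs(ct[, "t value"])))
        subjCoefs <- coef(fit)$subject
        subjCoefs <- data.frame(subject = rownames(subjCoefs),
                                subjCoefs, check.names = FALSE)
    }
    endpoint <- if (form == "linear_age")
        unname(fe["ageTerm"] * (8 - 33)) else
        unname(fe["ageTerm"] * (1 / 8 - 1 / 33))
    new("TrajectoryFit", fixef = fe,
        fixefTable = as.data.frame(ct),
        subjectCoefs = subjCoefs,
        logLik = as.numeric(logLik(fit)), aic = AIC(fit), form = form,
        endpointChange = endpoint, model = fit)
}

#' Mean-matched biased subsampling of two session groups
#'
#' Bootstrap control for a motion confound: sessions are resampled with
#' weights on framewise-displacement bins (20 equal-count bins over the
#' pooled FD) chosen so the resampled group A has higher mean FD than
#' group B (or the reverse). Returns the bootstrap distributions of the
#' group means of \code{y}, their difference, and a 95 percent CI, so a
#' group difference in \code{y} can be tested under a reversed motion
#' bias.
#'
#' @param groupA,groupB data.frames with numeric columns \code{y} and
#'   \code{fd}.
#' @param biasDirection "a_gt_b" (group A biased toward high FD) or
#'   "b_gt_a".
#' @param nBoot bootstrap draws.
#' @param nBins FD bins for the weighting.
#' @param seed integer seed.
#' @return list with meanYA, meanYB, diff (bootstrap vectors), ci95,
#'   meanFdA, meanFdB, achievedFdBias.
#' @export
meanMatchSubsample <- function(groupA, groupB,
                               biasDirection = c("a_gt_b", "b_gt_a"),
                               nBoot = 2000, nBins = 20, seed = NULL) {
    biasDirection <- match.arg(biasDirection)
    stopifnot(nrow(groupA) > 0, nrow(groupB) > 0)
    fdAll <- c(groupA$fd, groupB$fd)
    breaks <- unique(quantile(fdAll, seq(0, 1, length.out = nBins + 1)))
    binOf <- function(fd) pmax(1L, pmin(length(breaks) - 1L,
        findInterval(fd, breaks, rightmost.closed = TRUE)))
    bA <- binOf(groupA$fd); bB <- binOf(groupB$fd)
    nb <- length(breaks) - 1L
    ## quadratic bin weights push one group toward high-FD bins and the
    ## other toward low-FD bins
    if (biasDirection == "a_gt_b") {
        wA <- bA^2; wB <- (nb + 1 - bB)^2
    } else {
        wA <- (nb + 1 - bA)^2; wB <- bB^2
    }
    expA <- sum(wA * groupA$fd) / sum(wA)
    expB <- sum(wB * groupB$fd) / sum(wB)
    ok <- if (biasDirection == "a_gt_b") expA > expB else expB > expA
    if (!ok)
        stop("requested FD bias is unachievable for these FD supports")
    withSeed(seed, {
        nA <- nrow(groupA); nB <- nrow(groupB)
        meanYA <- meanYB <- fdA <- fdB <- numeric(nBoot)
        for (i in seq_len(nBoot)) {
            ia <- sample.int(nA, nA, replace = TRUE, prob = wA)
            ib <- sample.int(nB, nB, replace = TRUE, prob = wB)
            meanYA[i] <- mean(groupA$y[ia])
            meanYB[i] <- mean(groupB$y[ib])
            fdA[i] <- mean(groupA$fd[ia])
            fdB[i] <- mean(groupB$fd[ib])
        }
        dd <- meanYA - meanYB
        list(meanYA = meanYA, meanYB = meanYB, diff = dd,
             ci95 = unname(quantile(dd, c(0.025, 0.975))),
             meanFdA = fdA, meanFdB = fdB,
             achievedFdBias = mean(fdA) - mean(fdB))
    })
}

#' Correlation between individual brain and behavior trajectories
#'
#' Pearson correlation, across subjects with enough sessions, between
#' per-subject linear-age slopes of brain state variability and
#' per-subject inverse-age coefficients of a behavioral variability
#' measure. With the inverse-age convention, subjects stabilizing fastest
#' have the largest behavioral coefficients and the smallest (most
#' negative) brain slopes, so coupled stabilization appears as a negative
#' correlation.
#'
#' @param brainSlopes named numeric, per-subject linear-age slopes.
#' @param behaviorCoeffs named numeric, per-subject inverse-age
#'   coefficients.
#' @return list with r, p, n.
#' @export
individualSlopeCorrelation <- function(brainSlopes, behaviorCoeffs) {
    subj <- intersect(names(brainSlopes), names(behaviorCoeffs))
    if (length(subj) < 3) stop("fewer than 3 qualifying subjects")
    ct <- cor.test(brainSlopes[subj], behaviorCoeffs[subj])
    list(r = unname(ct$estimate), p = ct$p.value, n = length(subj))
}
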