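test_that("variance decomposition matches the projection-matrix oracle", {
    pat <- generateStatePatterns(100, seed = 51)
    msk <- brainMask(pat)
    nu <- buildNuisanceSet(NULL, msk)
    nv <- nVoxels(msk)
    ## residuals exactly equal to a state pattern: full attribution
    R <- matrix(statePatterns(pat)[, "vme_mean"], nv, 8)
    rs <- new("VolumeSeries", data = R, mask = msk, trSeconds = 1.5)
    vd <- decomposeVariance(rs, pat, nu, mgsTrs = c(2, 4), window = 0:1)
    expect_equal(totalBrainStateVariability(vd), 1, tolerance = 1e-9)
    expect_equal(vd@ssMaint, 0, tolerance = 1e-12)
    expect_equal(vd@ssRetrieval, 0, tolerance = 1e-12)
    ## residuals orthogonal to states and nuisance: zero attribution
    set.seed(52)
    X <- cbind(statePatterns(pat), nu@templates)
    P <- diag(nv) - X %*% solve(crossprod(X)) %*% t(X)
    Rp <- P %*% matrix(rnorm(nv * 6), nv, 6)
    rsp <- new("VolumeSeries", data = Rp, mask = msk, trSeconds = 1.5)
    vdp <- decomposeVariance(rsp, pat, nu, mgsTrs = c(1, 4),
                             window = 0:1)
    expect_equal(totalBrainStateVariability(vdp), 0, tolerance = 1e-9)
    ## random residuals against explicit projection matrices (the
    ## sequential orthogonal-complement projectors)
    Rr <- matrix(rnorm(nv * 10), nv, 10)
    rsr <- new("VolumeSeries", data = Rr, mask = msk, trSeconds = 1.5)
    vdr <- decomposeVariance(rsr, pat, nu, mgsTrs = c(2, 8),
                             window = 0:1)
    Xn <- nu@templates
    projOn <- function(A) A %*% solve(crossprod(A)) %*% t(A)
    seqSS <- function(cols) {
        ## projector of [nuisance, states up to cols] minus projector
        ## without those state columns
        Xbefore <- cbind(Xn, statePatterns(pat)[, seq_len(min(cols) - 1),
                                                drop = FALSE])
        Xafter <- cbind(Xn, statePatterns(pat)[, seq_len(max(cols)),
                                               drop = FALSE])
        Y <- Rr[, c(2, 3, 8, 9)]
        sum((projOn(Xafter) %*% Y)^2) - sum((projOn(Xbefore) %*% Y)^2)
    }
    expect_equal(vdr@ssVme, seqSS(1:2), tolerance = 1e-8)
    expect_equal(vdr@ssMaint, seqSS(3:4), tolerance = 1e-8)
    expect_equal(vdr@ssRetrieval, seqSS(5:6), tolerance = 1e-8)
    ## exact additivity of the component decomposition
    expect_equal(ssBrain(vdr), vdr@ssVme + vdr@ssMaint + vdr@ssRetrieval)
    expect_error(decomposeVariance(rsr, pat, nu, mgsTrs = integer(0)),
                 "no correct MGS")
})

test_that("component SS grows monotonically with its injected gain SD", {
    des <- mgsTaskDesign()
    pat <- generateStatePatterns(200, seed = 53)
    nu <- buildNuisanceSet(NULL, brainMask(pat))
    shares <- vapply(c(0.1, 0.25, 0.5), function(sdv) {
        gs <- rep(0.15, 6); gs[3:4] <- sdv
        tt <- gainGroundTruth(gainSd = gs, pIncorrect = 0)
        ses <- generateSession(des, tt, pat, seed = 54)
        fit <- firDeconvolve(ses$series, firDesign(des, ses$motion))
        vd <- decomposeVariance(fit$residuals, pat, nu,
                                ses$trials$mgs_tr_global)
        vd@ssMaint / (ssBrain(vd) + vd@ssError)
    }, numeric(1))
    expect_true(all(diff(shares) > 0))
})

test_that("trajectory fits recover noiseless coefficients and prefer the true form", {
    ages <- rep(seq(9, 30, length.out = 12), each = 2)
    subj <- rep(1:12, each = 2)
    d <- data.frame(y = 2 + 5 / ages, age = ages, subject = subj)
    fit <- suppressWarnings(fitTrajectory(d, "inverse_age"))
    expect_equal(unname(fit@fixef["(Intercept)"]), 2, tolerance = 1e-6)
    expect_equal(unname(fit@fixef["ageTerm"]), 5, tolerance = 1e-6)
    ## endpoint change from fixed effects only
    expect_equal(fit@endpointChange, 5 * (1 / 8 - 1 / 33),
                 tolerance = 1e-6)
    expect_equal(fit@aic, 2 * 4 - 2 * fit@logLik, tolerance = 1e-8)
    ## model comparison: linear-age data prefer the linear form
    set.seed(55)
    wins <- vapply(1:60, function(k) {
        n <- 40
        ages <- runif(n, 8, 33)
        d <- data.frame(y = 1 - 0.02 * ages + rnorm(n, 0, 0.05),
                        age = ages, subject = rep(1:20, 2))
        fl <- suppressWarnings(fitTrajectory(d, "linear_age"))
        fi <- suppressWarnings(fitTrajectory(d, "inverse_age"))
        fl@aic < fi@aic
    }, logical(1))
    expect_gte(mean(wins), 0.95)
    ## an uncorrelated covariate barely moves the age slope
    set.seed(56)
    n <- 60
    d2 <- data.frame(y = 1 - 0.01 * runif(n, 8, 33), subject = rep(1:30, 2))
    d2$age <- (1 - d2$y) / 0.01
    d2$y <- d2$y + rnorm(n, 0, 0.02)
    d2$fd <- runif(n, 0, 0.1)
    f0 <- suppressWarnings(fitTrajectory(d2, "linear_age"))
    f1 <- suppressWarnings(fitTrajectory(d2, "linear_age",
                                         covariates = "fd"))
    seSlope <- f0@fixefTable["ageTerm", "Std. Error"]
    expect_lt(abs(f1@fixef["ageTerm"] - f0@fixef["ageTerm"]),
              2 * seSlope)
    expect_error(fitTrajectory(data.frame(y = 1, age = 1, subject = 1)),
                 "at least 2 subjects")
})

test_that("mean-matched subsampling reverses FD bias but preserves y differences", {
    set.seed(57)
    nA <- 60; nB <- 60
    ## group A: older-like, lower FD, y lower by delta; y independent
    ## of FD within group
    delta <- -0.4
    groupA <- data.frame(fd = runif(nA, 0.02, 0.12),
                         y = 1 + delta + rnorm(nA, 0, 0.1))
    groupB <- data.frame(fd = runif(nB, 0.05, 0.15),
                         y = 1 + rnorm(nB, 0, 0.1))
    mm <- meanMatchSubsample(groupA, groupB, "a_gt_b", nBoot = 500,
                             seed = 58)
    ## the induced bias reverses the FD ordering
    expect_gt(mm$achievedFdBias, 0)
    ## the y difference survives: close to delta, CI excludes 0
    expect_lt(abs(mean(mm$diff) - delta), 0.1)
    expect_lt(mm$ci95[2], 0)
    ## identical groups: difference centered at zero, CI covers 0
    mm0 <- meanMatchSubsample(groupB, groupB, "a_gt_b", nBoot = 500,
                              seed = 59)
    expect_lt(abs(mean(mm0$diff)), 0.05)
    expect_true(mm0$ci95[1] < 0 && mm0$ci95[2] > 0)
    ## seeded reproducibility
    mm1 <- meanMatchSubsample(groupA, groupB, "a_gt_b", nBoot = 50,
                              seed = 60)
    mm2 <- meanMatchSubsample(groupA, groupB, "a_gt_b", nBoot = 50,
                              seed = 60)
    expect_identical(mm1$diff, mm2$diff)
    ## unachievable bias errors out
    lo <- data.frame(fd = rep(0.01, 10), y = rnorm(10))
    hi <- data.frame(fd = rep(0.50, 10), y = rnorm(10))
    expect_error(meanMatchSubsample(lo, hi, "a_gt_b"), "unachievable")
})

test_that("individual slope correlations behave under null and coupling", {
    ## exact negative linear function: r = -1
    bs <- setNames(seq(-0.01, 0.01, length.out = 10), paste0("s", 1:10))
    expect_equal(individualSlopeCorrelation(bs, -3 * bs)$r, -1)
    ## independent coefficients rarely reach |r| >= 0.5 with n = 29
    set.seed(61)
    extreme <- vapply(1:200, function(k) {
        a <- setNames(rnorm(29), paste0("s", 1:29))
        b <- setNames(rnorm(29), paste0("s", 1:29))
        abs(individualSlopeCorrelation(a, b)$r) >= 0.5
    }, logical(1))
    expect_lt(mean(extreme), 0.05)
    ## a shared latent stabilization factor induces the negative
    ## relationship at the designed effect size
    set.seed(62)
    latent <- rnorm(29)
    brain <- setNames(0.004 * latent + rnorm(29, 0, 0.002),
                      paste0("s", 1:29))
    behav <- setNames(-50 * latent + rnorm(29, 0, 25),
                      paste0("s", 1:29))
    got <- individualSlopeCorrelation(brain, behav)
    expect_lt(got$r, 0)
    expect_lt(got$p, 0.05)
    expect_error(individualSlopeCorrelation(bs[1:2], bs[1:2]),
                 "fewer than 3")
})
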