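test_that("saccade detection matches the brute-force scan oracle", {
    ## flat and all-zero traces yield no events
    expect_equal(nrow(detectSaccades(rep(0, 100))), 0)
    expect_equal(nrow(detectSaccades(rep(5, 100))), 0)
    ## single triangular pulse peaking at 100 deg/s: boundaries at the
    ## first samples below 10 deg/s on each flank
    v <- rep(1, 60)
    v[21:29] <- c(25, 50, 75, 100, 75, 50, 25, 12, 5)
    ev <- detectSaccades(v)
    expect_equal(nrow(ev), 1)
    expect_equal(ev$peak, 24)
    expect_equal(ev$start, 20)       # last sample below 10 before peak
    expect_equal(ev$end, 29)         # first sample below 10 after peak
    ## two well-separated pulses, in temporal order
    v2 <- rep(0, 120)
    v2[20:24] <- c(20, 60, 90, 60, 20)
    v2[80:84] <- c(20, 50, 70, 50, 20)
    ev2 <- detectSaccades(v2)
    expect_equal(nrow(ev2), 2)
    expect_true(ev2$peak[1] < ev2$peak[2])
    ## event-for-event agreement with the oracle on random traces
    set.seed(71)
    for (k in 1:50) {
        tr <- randomVelocityTrace()
        got <- detectSaccades(tr)
        want <- oracleDetectSaccades(tr)
        expect_equal(nrow(got), nrow(want))
        if (nrow(got)) {
            expect_equal(got$start, want$start)
            expect_equal(got$peak, want$peak)
            expect_equal(got$end, want$end)
        }
    }
})

test_that("trial scoring derives RT and SE from the traces", {
    rate <- 60
    n <- 1200
    vel <- rep(0, n); pos <- rep(0, n)
    ## trial 1: VGS at sample 100, fixation offset at 300, MGS starts
    ## exactly 300 ms later (18 samples)
    vel[100:104] <- c(20, 80, 120, 80, 20)
    mgsStart <- 300 + 18
    vel[mgsStart + 0:4] <- c(20, 90, 140, 90, 20)
    pos[(mgsStart + 4):n] <- 6          # endpoint on target
    ## trials 2 and 3: no MGS (incorrect), pushing their condition
    ## below the 50% measurable threshold
    vel[700:704] <- c(20, 70, 100, 70, 20)
    trials <- data.frame(
        target_onset_sample = c(80, 680, 1100),
        fixation_offset_sample = c(300, 900, 1150),
        response_end_sample = c(600, 1050, 1190),
        target_deg = c(6, -6, 6),
        presentation_s = c(1.5, 1.5, 1.5), delay_s = c(9, 9, 9))
    got <- scoreTrials(detectSaccades(vel), trials, pos)
    expect_equal(got$rt_ms[1], 300 - 1000 / 60, tolerance = 1e-6)
    expect_equal(got$se_deg[1], 0)
    expect_true(got$correct[1])
    expect_false(got$correct[2])
    ## 50% measurable trials in a condition flags the session
    expect_true(attr(got, "excludeSession"))
})

test_that("behavioral summaries compute the four metrics per condition", {
    tr <- data.frame(
        presentation_s = 1.5, delay_s = 9, hemifield = c(1, 1, -1, -1),
        eccentricity_deg = 6,
        rt_ms = c(400, 400, 500, 500),
        se_deg = c(0.5, -0.5, 1, 2), correct = TRUE)
    out <- behavioralSummaries(tr)
    expect_equal(out$meanRt, 450)
    expect_equal(out$sdRt, sd(c(400, 400, 500, 500)))
    ## target +6: SEs {0.5, -0.5} -> inaccuracy 0, imprecision 0.707;
    ## target -6: SEs {1, 2} -> inaccuracy 1.5, imprecision 0.707
    expect_equal(out$inaccuracy, mean(c(0, 1.5)))
    expect_equal(out$imprecision, mean(c(sd(c(0.5, -0.5)), sd(c(1, 2)))))
    ## identical RTs give zero SD; sparse cells give NA
    tr2 <- tr; tr2$rt_ms <- 400
    expect_equal(behavioralSummaries(tr2)$sdRt, 0)
    tr3 <- tr[1, ]
    expect_true(is.na(behavioralSummaries(tr3)$meanRt))
    ## estimated RT SD concentrates around the generator truth
    set.seed(72)
    sds <- vapply(1:20, function(k) {
        d <- data.frame(presentation_s = 1.5, delay_s = 9,
                        hemifield = 1, eccentricity_deg = 6,
                        rt_ms = rnorm(40, 500, 80),
                        se_deg = rnorm(40), correct = TRUE)
        behavioralSummaries(d)$sdRt
    }, numeric(1))
    expect_lt(abs(mean(sds) - 80), 3 * 80 / sqrt(2 * 40))
})

test_that("snippet extraction aligns relative TR 0 to the MGS", {
    des <- mgsTaskDesign()
    nTot <- des@nRuns * des@nTrPerRun
    trials <- des@trials
    trials$mgs_tr_global <- trials$mgs_tr +
        (trials$run - 1L) * des@nTrPerRun
    ## spike series: 1 exactly at each MGS TR for one component
    W <- matrix(0, 7, nTot)
    W[1, trials$mgs_tr_global] <- 1
    ex <- new("ExpressionSeries", weights = W, zscored = TRUE,
              trSeconds = 1.5)
    rownames(ex@weights) <- c(stateLabels(), "const")
    st <- extractSnippets(ex, trials, des@nTrPerRun)
    expect_true(all(st@values[, "0", "vme_mean"] == 1))
    ## away from overlaps, other columns are 0 or NA
    expect_true(all(st@values[, "15", "vme_mean"] %in% c(0, 1, NA)))
    ## out-of-run edges are NA-marked
    early <- which(trials$mgs_tr - 15 < 1)
    expect_true(all(is.na(st@values[early, "-15", "vme_mean"])))
    ## a single-trial stack keeps its center value
    one <- extractSnippets(ex, trials[1, ], des@nTrPerRun)
    expect_equal(dim(one@values)[1], 1)
    expect_equal(unname(one@values[1, "0", "vme_mean"]), 1)
})

test_that("the profiled-ML engine agrees with lme4", {
    set.seed(73)
    n <- 120
    g <- factor(rep(1:6, each = 20))
    X <- cbind(1, rnorm(n), rnorm(n))
    y <- 0.5 + X[, 2] - 0.3 * X[, 3] + rep(rnorm(6, 0, 0.4), each = 20) +
        rnorm(n, 0, 0.7)
    eng <- statevar:::lmmRanIntFit(X, y, g)
    d <- data.frame(y = y, x1 = X[, 2], x2 = X[, 3], g = g)
    ref <- lme4::lmer(y ~ x1 + x2 + (1 | g), d, REML = FALSE)
    expect_equal(eng$dev, deviance(ref), tolerance = 1e-6)
    expect_equal(unname(eng$beta), unname(lme4::fixef(ref)),
                 tolerance = 1e-5)
    expect_equal(eng$theta, unname(lme4::getME(ref, "theta")),
                 tolerance = 1e-3)
})

test_that("trial-wise regression finds designed couplings and respects nesting", {
    ## construct a stack directly: 8 subjects x 30 trials, maintenance
    ## fluctuation at TR 0 coupled to RT
    set.seed(74)
    nS <- 8; nT <- 30
    n <- nS * nT
    trials <- data.frame(
        subject = rep(1:nS, each = nT), session = rep(1:nS, each = nT),
        run = sample(1:3, n, TRUE), hemifield = sample(c(-1, 1), n, TRUE),
        eccentricity = sample(1:3, n, TRUE),
        presentation_s = sample(c(1.5, 3), n, TRUE),
        delay_s = sample(c(1.5, 9), n, TRUE),
        correct = TRUE)
    vals <- array(rnorm(n * 31 * 6), c(n, 31, 6),
                  dimnames = list(NULL, as.character(-15:15),
                                  stateLabels()))
    maint0 <- vals[, "0", "maint_mean"]
    trials$rt_ms <- 500 - 60 * maint0 + rnorm(n, 0, 60) +
        rep(rnorm(nS, 0, 30), each = nT)
    trials$se_deg <- rnorm(n, 0, 0.8)
    stack <- new("SnippetStack", values = vals, trials = trials,
                 halfWidth = 15L)
    fit0 <- trialwiseRegression(stack, "rt", 0, nSim = 200, seed = 75)
    expect_gt(fit0$deltaR2, 0.05)
    expect_lt(fit0$p, 0.01)
    ## the maintenance coefficient is negative (faster with greater
    ## expression)
    cf <- fit0$coefTable
    expect_lt(cf$estimate[cf$term == "maint_mean"], 0)
    ## an uncoupled relative TR carries no signal
    fit5 <- trialwiseRegression(stack, "rt", 8, nSim = 0)
    expect_lt(fit5$deltaR2, 0.05)
    ## delta R2 is nonnegative up to numerical epsilon for nested fits
    expect_gt(fit0$deltaR2, -1e-10)
    expect_gt(fit5$deltaR2, -1e-10)
    ## profile covers the requested TRs
    pr <- trialwiseProfile(stack, "rt", -2:2)
    expect_equal(pr$relTr, -2:2)
    expect_equal(which.max(pr$deltaR2), 3)
    expect_warning(trialwiseRegression(stack, "rt", 0, nSim = 50,
                                       seed = 1), "coarse")
})

test_that("speed-accuracy quadratic coefficient is recovered", {
    set.seed(76)
    rtZ <- rnorm(300)
    ## exact quadratic: coefficient 1, p ~ 0
    got <- speedAccuracyQuadratic(rtZ, rtZ^2 + rnorm(300, 0, 1e-4))
    expect_equal(got$coefficient, 1, tolerance = 1e-4)
    expect_lt(got$p, 1e-10)
    ## independence: coefficient within 2 SE of zero in most nulls
    cover <- vapply(1:100, function(k) {
        se <- rnorm(300)
        g <- speedAccuracyQuadratic(rtZ, se)
        abs(g$coefficient) < 2 * g$stdError
    }, logical(1))
    expect_gte(mean(cover), 0.90)
    ## U-shaped generator recovers a positive coefficient
    se <- 0.3 * rtZ^2 + rnorm(300, 0, 0.2)
    expect_gt(speedAccuracyQuadratic(rtZ, se)$coefficient, 0.2)
    expect_error(speedAccuracyQuadratic(rtZ[1:5], rtZ[1:5]), "at least")
    expect_error(speedAccuracyQuadratic(rep(1, 20), rnorm(20)),
                 "degenerate")
})
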