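test_that("generated patterns are mirror symmetric/antisymmetric and rank 6", {
    pat <- statePatterns(smallPatterns)
    pair <- smallMask@pairing
    for (s in c("vme", "maint", "retr")) {
        m <- pat[, paste0(s, "_mean")]
        sp <- pat[, paste0(s, "_spatial")]
        expect_identical(m[pair], m)          # exact symmetry
        expect_identical(sp[pair], -sp)       # exact antisymmetry
    }
    ## centering and unit norm
    expect_lt(max(abs(colMeans(pat))), 1e-12)
    expect_equal(unname(sqrt(colSums(pat^2))), rep(1, 6),
                 tolerance = 1e-12)
    ## independence checked through an SVD oracle
    sv <- svd(generateStatePatterns(500, seed = 1)@patterns)
    expect_equal(sum(sv$d > 1e-8 * sv$d[1]), 6)
    expect_error(generateStatePatterns(5), "at least 10")
})

test_that("session signal is exactly linear in the gains", {
    des <- mgsTaskDesign(nRuns = 1)
    s1 <- generateSession(des, silentTruth, smallPatterns, seed = 4)
    d1 <- s1$series@data
    expect_equal(dim(d1), c(nVoxels(smallMask), des@nTrPerRun))
    ## reconstruct the whole series from the realized gains with an
    ## independent shift-and-add convolution oracle; exact agreement
    ## demonstrates the signal is linear in the gains
    kernel <- hrfKernel(1.5, 21)
    nT <- des@nTrPerRun
    recon <- matrix(0, nVoxels(smallMask), nT)
    addEv <- function(recon, pattern, gain, at) {
        ## direct convolution oracle: shift-and-add of the kernel
        hx <- numeric(nT + length(kernel))
        hx[at + seq_along(kernel) - 1L] <- gain * kernel
        recon + silentTruth@amplitude * outer(pattern, hx[seq_len(nT)])
    }
    pat <- statePatterns(smallPatterns)
    for (i in seq_len(nrow(s1$trials))) {
        tri <- s1$trials[i, ]
        presTr <- round(tri$presentation_s / 1.5)
        delayTrs <- seq(min(max(tri$encode_tr + presTr + 2,
                                tri$encode_tr + 4), tri$mgs_tr - 1),
                        tri$mgs_tr - 1)
        recon <- addEv(recon, pat[, "vme_mean"], s1$gains[i, "vme_mean"],
                       tri$encode_tr)
        recon <- addEv(recon, pat[, "vme_spatial"],
                       s1$gains[i, "vme_spatial"], tri$encode_tr)
        dW <- if (length(delayTrs) == 1) 1 else
            seq(3, 1, length.out = length(delayTrs))
        for (di in seq_along(delayTrs)) {
            recon <- addEv(recon, pat[, "maint_mean"],
                           s1$gains[i, "maint_mean"] * dW[di],
                           delayTrs[di])
            recon <- addEv(recon, pat[, "maint_spatial"],
                           s1$gains[i, "maint_spatial"] * dW[di],
                           delayTrs[di])
        }
        recon <- addEv(recon, pat[, "retr_mean"],
                       s1$gains[i, "retr_mean"], tri$mgs_tr)
        recon <- addEv(recon, pat[, "retr_spatial"],
                       s1$gains[i, "retr_spatial"], tri$mgs_tr)
    }
    expect_lt(max(abs(d1 - recon)), 1e-6)
})

test_that("zero gain variability and zero noise give a flat residual field", {
    des <- mgsTaskDesign(nRuns = 1)
    ses <- generateSession(des, silentTruth, smallPatterns, seed = 7)
    ## all trials of a cell are identical, so FIR residuals vanish
    ## (no motion columns: the session has exactly zero motion)
    fit <- firDeconvolve(ses$series, firDesign(des, NULL))
    expect_lt(max(abs(fit$residuals@data)), 1e-6)
})

test_that("behavior decouples from gains when couplings are zero", {
    tt <- gainGroundTruth(rtCoupling = rep(0, 6),
                          seCoupling = rep(0, 6), pIncorrect = 0)
    cors <- vapply(1:10, function(k) {
        ses <- generateSession(smallDesign, tt, smallPatterns,
                               seed = 100 + k)
        cor(ses$gains[, "maint_mean"], ses$trials$rt_ms)
    }, numeric(1))
    ## mean correlation over seeded sessions converges to zero
    expect_lt(abs(mean(cors)), 2 / sqrt(10 * nrow(smallDesign@trials)))
})

test_that("noise-free expression recovers gain-scaled HRF time courses", {
    des <- mgsTaskDesign(nRuns = 1)
    tt <- gainGroundTruth(gainSd = rep(0.3, 6), noiseSd = 1e-9,
                          driftSd = 0, motionAmplitudeMm = 0,
                          motionArtifactScale = 0, pIncorrect = 0,
                          timingJitter = FALSE)
    ses <- generateSession(des, tt, smallPatterns, seed = 11)
    ## least-squares projection of the series on the true patterns
    W <- qr.coef(qr(statePatterns(smallPatterns)), ses$series@data)
    kernel <- hrfKernel(1.5, 21)
    nT <- des@nTrPerRun
    ## oracle: per-component convolution of the gain-weighted events
    for (comp in c("vme_mean", "retr_mean")) {
        ev <- numeric(nT)
        at <- if (comp == "vme_mean") ses$trials$encode_tr else
            ses$trials$mgs_tr
        ev[at] <- ses$gains[, comp]
        oracle <- tt@amplitude *
            statevar:::convolveEvents(ev, kernel)
        expect_equal(unname(W[comp, ]), oracle, tolerance = 1e-6)
    }
})

test_that("cohort gain SDs follow the age model and runs are reproducible", {
    coh <- generateCohort(8, gainSdSlope = rep(0, 6), subjectSd = 0,
                          nVoxelsPerHemisphere = 20, seed = 5,
                          sessionsPerSubject = 1)
    expect_equal(length(unique(round(coh$table$vme_mean, 12))), 1)
    cohNeg <- generateCohort(20, gainSdSlope = rep(-0.005, 6),
                             subjectSd = 0, nVoxelsPerHemisphere = 20,
                             seed = 5, sessionsPerSubject = 1)
    expect_lt(cor(cohNeg$table$age, cohNeg$table$maint_mean,
                  method = "spearman"), 0)
    ## determinism: identical seed, identical output
    a <- generateCohort(3, nVoxelsPerHemisphere = 20, seed = 9,
                        sessionsPerSubject = 1)
    b <- generateCohort(3, nVoxelsPerHemisphere = 20, seed = 9,
                        sessionsPerSubject = 1)
    expect_identical(a$table, b$table)
    expect_identical(a$sessions[[1]]$series@data,
                     b$sessions[[1]]$series@data)
    expect_error(generateCohort(5, gainSdSlope = rep(NaN, 6),
                                nVoxelsPerHemisphere = 20),
                 "finite")
})
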