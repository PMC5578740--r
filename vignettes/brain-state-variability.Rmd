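---
title: "Measuring brain state variability in task fMRI"
author: "statevar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring brain state variability in task fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Performance of a memory-guided saccade (MGS) task engages three
separable processes — a visuomotor/encoding (VME) transient around the
initial visually guided saccade, sustained working-memory maintenance
over the delay, and retrieval/response activity around the MGS. Each is
associated with a reproducible whole-brain spatial pattern of BOLD
activity, a *brain state*. A global gain signal, by definition, does not
change a pattern's spatial layout; it scales the *amplitude* with which
the pattern is expressed. The package operationalizes this as a linear
generative model on a masked voxel set:

    BOLD(v, t) = sum_c pattern_c(v) * x_c(t) + drift + motion + noise

where each component `c` is one of six patterns (three states, each
split into a hemifield-average "mean" component and a right-minus-left
"spatial" component) and `x_c(t)` is a per-trial gain times an HRF time
course anchored at that component's task event. Trial-to-trial variance
of the gains is *brain state variability*; the package measures it, maps
its developmental trajectory, and relates it to behavior (reaction time
RT, signed saccadic error SE).

All pipeline stages operate on that model's terms:

1.  **FIR deconvolution** estimates per-condition average trial time
    courses voxel-wise (0/1 impulse regressors over the trial duration
    plus 15 TRs), with third-order Legendre drift per run and 28
    lead/lag motion regressors (7 motion series x lags -1, 0, +1, +2).
    Trial averages are rescaled by each voxel's residual SD.
2.  **State extraction** pulls single volumes from the long-delay trial
    averages: VME and retrieval at their events plus a 4 TR (6 s)
    hemodynamic lag, maintenance at the TR before the MGS. Maintenance
    patterns are residualized on the VME source patterns (optionally
    also the encoding-saccade volumes); retrieval patterns on every
    pre-MGS volume.
    Each state is decomposed into mean and spatial components, mirror
    symmetrized, centered and scaled to unit norm.
3.  **Nuisance templates**: principal components of the (residual-SD
    normalized, centered, norm-equalized) lagged-motion coefficient
    maps up to >90% cumulative variance, plus two constants and six
    spatial gradient/product templates.
4.  **Projection** regresses each whole-brain volume on the six states
    plus the nuisance templates jointly; applied per TR to the average
    trial series this yields expression time courses, applied to the
    residual series it yields fluctuation time courses (z-scored per
    session).
5.  **Variance decomposition** over TRs 0-5 after each correct MGS
    splits residual squared error into SS_VME + SS_Maint + SS_Retrieval
    (= SS_brain), SS_motion, other-nuisance and SS_error on a
    sequentially orthonormalized basis, making the additivity exact.
    Total brain state variability is SS_brain / (SS_brain + SS_error).
6.  **Trajectories and behavior**: linear mixed models (random subject
    intercept, ML) of session-level ratios on age with mean framewise
    displacement and correct-trial count as covariates; MGS-aligned
    snippet regressions of trial behavior on state fluctuations with a
    simulated (parametric bootstrap) likelihood-ratio test; and the
    timing/amplitude mechanism simulations.

## What the synthetic generator emulates

The generator is the package's test bed and defines its study
conditions. It draws six ground-truth patterns on a mirror-paired mask
(exactly symmetric mean components, antisymmetric spatial components),
then synthesizes sessions of the real task's structure: 3 runs, the four
presentation x delay conditions (1.5/3 s presentation, 1.5/9 s delay)
crossed with hemifield in every run, eccentricities cycling 3/6/9
degrees, TR 1.5 s. Defaults that the task or the field fixes are kept
(TR, conditions, the 15 TR FIR tail); quantities the task does not fix
are configuration with documented defaults:

-   **Trials and spacing**: 8 trials per run (one per condition x
    hemifield), inter-trial gap 16 TRs, runs of roughly 175 TRs. The
    source task's exact trial counts are not public; these values give
    runs of the right length and balanced cells.
-   **Gains**: mean 1 (mean components) or the hemifield sign (spatial
    components), SD 0.25 by default — large enough that state
    fluctuations account for a few percent of residual whole-brain
    variance, the order of magnitude seen in task fMRI.
-   **Amplitude and noise**: unit-norm patterns expressed at amplitude
    20 (a.u.) against i.i.d. voxel noise SD 1.
-   **Maintenance time course**: delay-spanning activity convolved with
    the HRF, so long and short delays produce sustained versus
    transient expression. The activity onsets 2 TRs after stimulus
    offset and never earlier than 4 TRs (one hemodynamic lag) after the
    encoding saccade — modelling the ramp from the visuomotor transient
    to sustained delay activity, and guaranteeing the volume the VME
    pattern is extracted from contains exactly zero delay activity
    (patterns expressed near-simultaneously cannot be separated by any
    extraction procedure). The activity has an onset transient decaying
    3:1 toward the saccade, a standard delay-period profile; it also
    places the delay activity's hemodynamic influence on the MGS window
    just after the saccade, where the trial-wise brain/behavior
    association is empirically observed to peak.
-   **Latency coupling**: by default the retrieval event is expressed
    at the trial's actual response time (the MGS TR plus the trial's RT
    deviation, HRF sampled continuously), so brain/behavior coupling
    mixes amplitude and latency components as the mechanism analyses
    conclude for real data; `timingJitter = FALSE` switches to a purely
    amplitude-coupled generator for exact-convolution oracles.
-   **HRF**: double-gamma with peak at 6 s, undershoot at 16 s,
    undershoot ratio 1/6, unit peak. Within the generator the kernel is
    truncated at 15 TRs (21 s, ~3% of peak), which keeps every event's
    response inside the FIR modelling window; the mechanism simulations
    use the full 30 s kernel at 60 ms resolution.
-   **Behavior**: RT = 500 ms + coupling x gain deviations + noise
    (SD 80 ms); SE analogous (SD 0.8 deg). Default couplings: faster
    responses with greater VME and maintenance mean expression (-50 and
    -100 ms per unit gain), larger errors with greater VME expression
    (+0.3 deg) — the sign structure the trial-wise analyses probe.
-   **Cohorts**: subject ages uniform on 8-33 years; injected gain SD
    linear in age plus subject-level noise (SD 0.02). The recovery
    analyses use maintenance/retrieval SD falling from 0.35 at age 8 by
    0.006/year (~40% over the age range, the order of the reported
    behavioral declines) with VME flat at 0.25, and 3 trials per
    condition-hemifield cell per run (72 per session): a session-level
    gain-SD estimand has sampling CV of (2(n-1))^(-1/2), so ~50+ trials
    are needed before measurement error stops swamping the
    between-subject signal a recovery analysis must resolve.
-   **Ground-truth patterns are orthonormal**: the canonical states the
    generator emulates are themselves sequentially orthogonalized, so
    after the mirror construction (which makes mean and spatial
    components exactly orthogonal) the mean components are
    Gram-Schmidt-orthogonalized across states and likewise the spatial
    components. With correlated ground-truth patterns the shared
    direction's variance would be attributed to whichever component is
    ordered first — a property of non-orthogonal decompositions, not of
    the estimator.
-   **Nuisance structure**: per-voxel random third-order Legendre drift
    (coefficient SD 0.5), motion parameters as per-run random walks
    (increment SD 0.02 mm) with seven random spatial artifact patterns
    scaled by 0.5 a.u., and 5% unmeasurable trials.

What the generator does **not** emulate: spatial autocorrelation beyond
a 1-D smoothness kernel, physiological (cardiac/respiratory) noise,
realistic anatomy or registration error, nonlinear HRF effects, and
task-correlated motion. Green tests therefore certify the estimation
machinery — linear-algebra correctness, calibration of the tests,
recovery under the stated signal model — not robustness to every
artifact structure of real data.

## Numerical choices

-   All regressions are OLS (or GLS for mixed models) through pivoted
    QR with a 1e-10 relative tolerance; rank deficiency is an explicit
    error naming the collinear columns, never a silent drop.
-   Component sums of squares use sequential orthonormalization in the
    fixed order nuisance, VME, maintenance, retrieval (mean before
    spatial), so SS_brain additivity is exact and attribution is "net
    of everything earlier", matching the states' construction order.
-   The orthogonalization reference sets are closed under the mirror
    pairing before residualization; this makes the later mirror
    symmetrization exactly commute with orthogonality (a mirrored
    reference is still a reference), so both invariants hold to
    machine precision simultaneously.
-   Lead/lag motion shifts replicate the boundary sample at run edges.
-   The saccade detector takes local velocity maxima above a 30 deg/s
    floor (the source describes no floor; 30 deg/s sits well below any
    plausible MGS peak velocity and above tracker noise) and walks
    outward to the first samples below peak/10; candidates inside an
    accepted event are skipped, so events never overlap.
-   Trial behavior is z-scored within session x condition; SE as a
    response is additionally rectified (absolute z-score), so larger
    values always mean larger error.
-   The simulated likelihood-ratio test is a parametric bootstrap of
    the fitted null model in which both models are refit per draw. The
    refits use an exact closed-form profiled-ML evaluator for the
    random-intercept Gaussian LMM (the covariance is block diagonal, so
    GLS whitening per subject is closed form and the deviance profiles
    to a 1-D optimization); it agrees with lme4's ML deviance to
    numerical precision (tested) and makes thousands of refits
    affordable. User-facing trajectory fits use lme4 itself.
-   Mechanism classification: a pure amplitude mechanism yields a
    fast-minus-slow integral difference exactly proportional to the
    cumulative HRF (closed form), and a pure timing mechanism yields
    terminal integrals of zero. "Converged to zero" means below 5% of
    the amplitude-mode oracle magnitude for the same RTs; timing
    admixture is declared when the relative least-squares misfit to the
    amplitude shape exceeds 5%. Degenerate inputs (no RT variance)
    return "indeterminate" rather than a guess.
-   Mean-matched subsampling weights sessions by quadratic scores on 20
    equal-count FD bins (the cited technique names no parameters); the
    achieved bias is verified and an unachievable bias is an error.

## Design decisions taken where the design was open

-   The voxel-wise mixed-effects idealized time courses of the source
    analysis are replaced by a covariate-adjusted fixed-effects group
    average (mean-centered age, displacement, incorrect-trial
    proportion; prediction at mean age, zero displacement, perfect
    performance). At cohort sizes used here the estimand is identical;
    the random-effect term only reweights subjects. When there are too
    few sessions to support covariates the plain group mean is used.
-   Mirroring is an exact voxel pairing carried by the mask rather than
    a registration-based geometric reflection; for NIfTI masks the
    pairing is the first-axis index reflection with non-paired voxels
    dropped. This removes registration software from the contract while
    preserving the symmetrization semantics.
-   Maintenance orthogonalization references default to the VME source
    patterns; the encoding-saccade-TR volumes are available via
    `includeEncodeRefs`. When no task activity precedes the encoding
    saccade those volumes contain only trial-average estimation noise,
    and because that noise is spatially correlated with the later-lag
    estimates, regressing on it strips real maintenance signal rather
    than visuomotor signal. For data with appreciable pre-saccade
    stimulus activity the fuller reference set is the right choice.
-   The motion-template count is data-determined by the >90% rule; 11
    is a property of the source data set, and the structural "19
    nuisance regressors" identity is asserted for k = 11. When no
    distinct state mask exists the duplicate state-mask constant is
    dropped to keep the design full rank.
-   Subject random effects: random intercepts everywhere; a random age
    slope only where individual slopes are extracted (4+ sessions per
    subject), mirroring the source's usage.
-   Sessions failing the 50%-measurable filter are flagged, not
    silently dropped; incorrect trials still enter the FIR design (as
    stated) and only correct trials enter snippets and variance
    windows.

## Problem sizes

The bundled analyses run at desk scale, chosen so the full suite
completes in minutes while every estimator operates above its small-n
regime: validation cohorts of 20 subjects x 2 sessions at 2,000 voxels
for trajectory-sign and recovery checks (state-pattern recovery
exceeds |cos| 0.95 at this scale), 200-replicate type-I calibration of
the simulated LRT at 500 bootstrap draws, and 5,000 draws for single
peak tests. The estimators themselves are dimension-agnostic; real
whole-brain masks (~10^5 voxels) change only runtime.

## Known limitations

-   Component attribution inherits any residual cross-talk between
    extracted states; the sequential orthogonalization bounds it but
    the VME state is never residualized (by design, following the
    source construction), so VME shares can absorb maintenance signal
    when the two are expressed close in time.
-   The profiled-ML engine covers random intercepts only; models with
    random slopes go through lme4 and are not bootstrapped.
-   `p` values for mixed-model fixed effects use the normal
    approximation to the t statistic; with the session counts used
    here the approximation is mild, but small-sample inference should
    rely on the simulated LRT instead.
-   Real-data mode expects preprocessed, MNI-registered, masked NIfTI
    input; no preprocessing is performed or wrapped.
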