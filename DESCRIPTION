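Package: statevar
Title: Brain State Variability Analysis for Task fMRI
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for decomposing trial-to-trial variability in task fMRI
    into fluctuations in the amplitude of expression of canonical whole-brain
    task states. Provides finite impulse response (FIR) deconvolution with
    drift and lagged motion nuisance structure, extraction of mean and
    spatial brain-state components for the epochs of a memory-guided saccade
    task, motion-artifact template construction, per-volume pattern
    projection, sums-of-squares variance decomposition with developmental
    trajectory fitting, trial-wise brain/behavior regression with a simulated
    likelihood-ratio test, latency-versus-amplitude reaction-time
    simulations, and a synthetic gain-modulated BOLD generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    lme4,
    RNifti,
    yaml,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, Visualization, FunctionalGenomics
RoxygenNote: 7.3.3
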