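#' Write a synthetic session to standard formats
#'
#' BOLD as 4D float32 NIfTI-1 plus a mask NIfTI, trials and motion as
#' headered CSV, and the realized ground truth as a YAML/CSV sidecar
#' pair.
#'
#' @param session a \code{\link{generateSession}} result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the named vector of written paths.
#' @export
writeSession <- function(session, dir, prefix = "session") {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    mask <- session$series@mask
    nT <- ncol(session$series@data)
    vol4 <- array(0, dim = c(mask@dim, nT))
    step <- prod(mask@dim)
    for (t in seq_len(nT))
        vol4[(t - 1L) * step + mask@active] <- session$series@data[, t]
    paths <- c(
        bold = file.path(dir, paste0(prefix, "_bold.nii")),
        mask = file.path(dir, paste0(prefix, "_mask.nii")),
        trials = file.path(dir, paste0(prefix, "_trials.csv")),
        motion = file.path(dir, paste0(prefix, "_motion.csv")),
        truth = file.path(dir, paste0(prefix, "_truth.yaml")),
        gains = file.path(dir, paste0(prefix, "_gains.csv")))
    RNifti::writeNifti(RNifti::asNifti(vol4, datatype = "float"),
                       paths["bold"])
    RNifti::writeNifti(
        RNifti::asNifti(maskedToArray(mask, rep(1, nVoxels(mask))),
                        datatype = "uint8"), paths["mask"])
    utils::write.csv(session$trials, paths["trials"], row.names = FALSE)
    mot <- cbind(as.data.frame(session$motion@params),
                 total_displacement = session$motion@totalDisplacement)
    utils::write.csv(mot, paths["motion"], row.names = FALSE)
    tt <- session$truth
    yaml::write_yaml(list(
        gain_sd = as.list(tt@gainSd),
        rt_coupling_ms = as.list(tt@rtCoupling),
        se_coupling_deg = as.list(tt@seCoupling),
        rt_base_ms = tt@rtBaseMs, amplitude = tt@amplitude,
        noise_sd = tt@noiseSd), paths["truth"])
    utils::write.csv(as.data.frame(session$gains), paths["gains"],
                     row.names = FALSE)
    invisible(paths)
}

#' Read a trial table or motion series written by \code{writeSession}
#'
#' @param path CSV path.
#' @return \code{readTrialTable}: a data.frame; \code{readMotionSeries}:
#'   a \linkS4class{MotionSeries}.
#' @export
readTrialTable <- function(path) {
    utils::read.csv(path)
}

#' @rdname readTrialTable
#' @export
readMotionSeries <- function(path) {
    d <- utils::read.csv(path)
    new("MotionSeries",
        params = as.matrix(d[, c("trans_x", "trans_y", "trans_z",
                                 "rot_x", "rot_y", "rot_z")]),
        totalDisplacement = d$total_displacement)
}

#' Read a 4D BOLD NIfTI restricted to a mask
#'
#' @param boldPath 4D NIfTI path.
#' @param mask a \linkS4class{BrainMask} (e.g. from
#'   \code{\link{maskFromNifti}}).
#' @param trSeconds TR duration.
#' @return a \linkS4class{VolumeSeries}.
#' @export
readVolumeSeries <- function(boldPath, mask, trSeconds = 1.5) {
    img <- RNifti::readNifti(boldPath)
    d <- dim(img)
    stopifnot(length(d) == 4, all(d[1:3] == mask@dim))
    step <- prod(d[1:3])
    data <- vapply(seq_len(d[4]), function(t)
        img[(t - 1L) * step + mask@active], numeric(nVoxels(mask)))
    new("VolumeSeries", data = data, mask = mask, trSeconds = trSeconds)
}

## Run one session through deconvolution, returning the fit plus the
## session covariates the state-extraction step needs.
.sessionFit <- function(ses, design) {
    fd <- framewiseDisplacement(ses$motion)
    dm <- firDesign(design, ses$motion)
    fit <- firDeconvolve(ses$series, dm)
    fit$meanFd <- fd$meanFd
    fit$incorrectProp <- mean(!ses$trials$correct)
    fit
}

#' Run the full brain-state variability pipeline on a synthetic cohort
#'
#' Orchestrates the stages end to end: cohort simulation, per-session
#' FIR deconvolution, canonical state estimation from the long-delay
#' trial averages, motion-template and gradient nuisance construction,
#' residual projection, per-session variance decomposition, and
#' trajectory fits of total and per-component brain state variability.
#' Stage outputs are written as headered CSV tables plus a JSON manifest
#' with parameters, seeds and per-file checksums.
#'
#' @param config a named list (or YAML file path) with elements
#'   \code{simulate} (arguments for \code{\link{generateCohort}}), or --
#'   for real-data mode -- \code{sessions}: a list of per-session path
#'   sets (\code{bold}, \code{mask}, \code{trials}, \code{motion}, plus
#'   \code{subject}, \code{age}); and stage parameters \code{lagTr},
#'   \code{window}, \code{varianceTarget}, \code{seed}, \code{out}
#'   (output directory; NULL to skip writing).
#' @return list with cohort table, states, nuisance, per-session
#'   decompositions, trajectory fits and the manifest.
#' @export
runPipeline <- function(config = list()) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfg <- utils::modifyList(list(
        simulate = list(nSubjects = 6), lagTr = 4L, window = 0:5,
        varianceTarget = 0.90, r2Thresh = 0, seed = 1,
        out = NULL), config)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    if (!is.null(cfg$sessions)) {
        ## real-data mode: validate the config before any computation
        for (s in cfg$sessions)
            for (f in c("bold", "mask", "trials", "motion")) {
                if (is.null(s[[f]]))
                    stop("config validation: session entry lacks '",
                         f, "'")
                if (!file.exists(s[[f]]))
                    stop("config validation: missing file ", s[[f]])
            }
        mask <- maskFromNifti(cfg$sessions[[1]]$mask)
        loadOne <- function(s) {
            trials <- readTrialTable(s$trials)
            motion <- readMotionSeries(s$motion)
            series <- readVolumeSeries(s$bold, mask)
            nRuns <- max(trials$run)
            design <- new("TaskDesign", trials = trials[, c(
                "run", "presentation_s", "delay_s", "hemifield",
                "eccentricity_deg", "eccentricity", "encode_tr",
                "mgs_tr")],
                nRuns = as.integer(nRuns),
                nTrPerRun = as.integer(ncol(series@data) / nRuns),
                trSeconds = series@trSeconds)
            list(series = series, trials = trials, motion = motion,
                 design = design,
                 subject = if (is.null(s$subject)) NA else s$subject,
                 age = if (is.null(s$age)) NA_real_ else s$age,
                 visit = if (is.null(s$visit)) 1L else s$visit)
        }
        sessions <- stage("load", lapply(cfg$sessions, loadOne))
        design <- sessions[[1]]$design
        cohort <- list(
            sessions = sessions,
            table = data.frame(
                subject = vapply(sessions, function(s)
                    as.character(s$subject), character(1)),
                visit = vapply(sessions, `[[`, numeric(1), "visit"),
                age = vapply(sessions, `[[`, numeric(1), "age")))
        fits <- stage("deconvolve",
                      lapply(cohort$sessions, .sessionFit,
                             design = design))
    } else {
        simArgs <- cfg$simulate
        simArgs$seed <- cfg$seed
        design <- if (!is.null(simArgs$design)) simArgs$design else
            mgsTaskDesign()
        simArgs$design <- design
        ## deconvolve each session as it is generated so raw BOLD
        ## series never accumulate across the cohort
        simArgs$processSession <- function(ses) {
            list(fit = .sessionFit(ses, design), trials = ses$trials,
                 gains = ses$gains, subject = ses$subject,
                 age = ses$age, visit = ses$visit)
        }
        cohort <- stage("simulate",
                        do.call(generateCohort, simArgs))
        mask <- cohort$patterns@mask
        fits <- lapply(cohort$sessions, `[[`, "fit")
    }

    covs <- data.frame(
        age = vapply(cohort$sessions, `[[`, numeric(1), "age"),
        displacement = vapply(fits, `[[`, numeric(1), "meanFd"),
        incorrectProp = vapply(fits, `[[`, numeric(1), "incorrectProp"))
    states <- stage("states",
                    estimateBrainStates(fits, covs, mask,
                                        lagTr = cfg$lagTr))

    nuisance <- stage("templates", {
        coefAvg <- Reduce(`+`, lapply(fits, function(f)
            f$motionCoef / f$residuals@residSd)) / length(fits)
        mt <- motionTemplates(coefAvg, rep(1, nVoxels(mask)),
                              cfg$varianceTarget)
        ## state-mask constant from the group-average model R-squared
        ## (synthetic masks have no gray-matter map: probability 1)
        groupR2 <- rowMeans(vapply(fits, `[[`, numeric(nVoxels(mask)),
                                   "r2"))
        sm <- buildStateMask(rep(1, nVoxels(mask)), groupR2,
                             r2Thresh = cfg$r2Thresh)
        buildNuisanceSet(mt, mask, stateMask = as.logical(sm))
    })

    decomps <- stage("variability", lapply(seq_along(fits), function(i) {
        tr <- cohort$sessions[[i]]$trials
        mgs <- tr$mgs_tr_global[tr$correct]
        decomposeVariance(fits[[i]]$residuals, states, nuisance,
                          mgsTrs = mgs, window = cfg$window)
    }))

    tab <- cohort$table
    tab$meanFd <- covs$displacement
    tab$nCorrect <- vapply(cohort$sessions, function(s)
        sum(s$trials$correct), numeric(1))
    tab$totalVariability <- vapply(decomps, totalBrainStateVariability,
                                   numeric(1))
    tab$vmeShare <- vapply(decomps, function(d)
        d@ssVme / (ssBrain(d) + d@ssError), numeric(1))
    tab$maintShare <- vapply(decomps, function(d)
        d@ssMaint / (ssBrain(d) + d@ssError), numeric(1))
    tab$retrShare <- vapply(decomps, function(d)
        d@ssRetrieval / (ssBrain(d) + d@ssError), numeric(1))

    canFit <- all(is.finite(tab$age)) &&
        length(unique(tab$subject)) >= 2 && nrow(tab) >= 3
    trajFits <- if (!canFit) NULL else stage("trajectories", {
        fitFor <- function(col) {
            d <- data.frame(y = tab[[col]], age = tab$age,
                            subject = tab$subject,
                            meanFd = tab$meanFd,
                            nCorrect = tab$nCorrect)
            fitTrajectory(d, "linear_age",
                          covariates = c("meanFd", "nCorrect"))
        }
        list(total = fitFor("totalVariability"),
             vme = fitFor("vmeShare"), maint = fitFor("maintShare"),
             retr = fitFor("retrShare"))
    })

    manifest <- list(
        package = as.character(utils::packageVersion("statevar")),
        seed = cfg$seed, lagTr = cfg$lagTr,
        window = as.integer(cfg$window),
        varianceTarget = cfg$varianceTarget,
        nSessions = length(fits),
        nMotionTemplates = sum(grepl("^motion_pc", nuisance@labels)))
    if (!is.null(cfg$out)) {
        dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
        sesPath <- file.path(cfg$out, "session_table.csv")
        utils::write.csv(tab, sesPath, row.names = FALSE)
        statePath <- file.path(cfg$out, "state_patterns.csv")
        utils::write.csv(as.data.frame(states@patterns), statePath,
                         row.names = FALSE)
        manifest$files <- as.list(tools::md5sum(c(sesPath, statePath)))
        jsonlite::write_json(manifest,
                             file.path(cfg$out, "manifest.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    list(table = tab, states = states, nuisance = nuisance,
         decompositions = decomps, trajectories = trajFits,
         cohort = cohort, fits = fits, manifest = manifest)
}
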