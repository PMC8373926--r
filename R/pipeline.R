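## End-to-end pipeline: simulate -> preprocess -> time-frequency contrast ->
## cluster permutation test -> components & scores -> reliability ->
## classification & clinical associations, with a validated run
## configuration and optional on-disk outputs.

#' Default pipeline run configuration
#'
#' Returns the full set of tunable pipeline parameters as a named list.
#' \code{scale = "full"} reproduces the emulated study's dimensions (38
#' participants, 96 trials each at 512 Hz, 1000 permutations) and takes
#' hours of CPU; \code{scale = "demo"} is a reduced configuration (12
#' participants, 20 trials at 128 Hz, coarser grid, 200 permutations) that
#' exercises every stage in about a minute and is the default for examples.
#'
#' @param scale \code{"full"} or \code{"demo"}.
#' @return named list; see \code{\link{validateRunConfig}} for the fields.
#' @export
defaultRunConfig <- function(scale = c("demo", "full")) {
  scale <- match.arg(scale)
  if (scale == "full") {
    list(
      nPd = 20, nControl = 18, nOdorTrials = 72, nSniffTrials = 24,
      fs = 512, epochWindow = c(-2, 2),
      freqs = seq(0.5, 100, by = 0.5), times = seq(-2, 2, by = 0.01),
      baselineWindow = c(-1.5, -0.5),
      burstAmp = 8, artifactRates = c(blink = 0.05, muscle = 0.05),
      notch = TRUE, delay = 0.150, muscleZ = 8, blinkZ = 4,
      alphaBin = 0.05, minSize = 100, alphaCluster = 0.05, nPerm = 1000,
      nSplits = 4, outcome = "odor_id", nBoot = 1000
    )
  } else {
    list(
      nPd = 6, nControl = 6, nOdorTrials = 14, nSniffTrials = 6,
      fs = 200, epochWindow = c(-1.5, 1.6),
      freqs = seq(4, 72, by = 4), times = seq(-0.9, 1.3, by = 0.05),
      baselineWindow = c(-0.9, -0.4),
      burstAmp = 8, artifactRates = c(blink = 0.02, muscle = 0.02),
      notch = TRUE, delay = 0, muscleZ = 8, blinkZ = 4,
      alphaBin = 0.05, minSize = 10, alphaCluster = 0.05, nPerm = 200,
      nSplits = 4, outcome = "odor_id", nBoot = 200
    )
  }
}

#' Validate and complete a pipeline run configuration
#'
#' Unknown fields are an error (catching typos); missing fields are filled
#' with the demo defaults.  \code{delayMs} is accepted as an alternative to
#' \code{delay} and converted to seconds.  Fewer than 100 permutations
#' triggers a warning about p-value resolution.
#'
#' @param config named list of overrides (possibly empty).
#' @param base base configuration to complete against (default
#'   \code{defaultRunConfig("demo")}).
#' @return completed configuration list.
#' @export
validateRunConfig <- function(config = list(), base = defaultRunConfig("demo")) {
  if (!is.null(config[["delayMs"]])) {
    if (!is.null(config[["delay"]])) stop("give 'delay' or 'delayMs', not both")
    config[["delay"]] <- config[["delayMs"]] / 1000
    config[["delayMs"]] <- NULL
  }
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) {
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  }
  out <- base
  out[names(config)] <- config
  if (out$nPerm < 100) warning("fewer than 100 permutations: coarse p resolution")
  if (out$baselineWindow[1L] < out$times[1L]) {
    stop("baseline window starts before the analysis time axis")
  }
  out
}

#' Run the complete analysis pipeline on synthetic data
#'
#' Simulates a cohort, preprocesses every participant, computes
#' odor-vs-sniff induced-power contrast maps, runs the cluster-based
#' permutation test, extracts and scores components, assesses trial-split
#' reliability (ICC(2,k)), classifies group with a mixed-effect logistic
#' model (forward stepwise component selection, AIC comparison), and tests
#' clinical associations with a subsample-bootstrap check.  Fully
#' deterministic given (config, seed).
#'
#' @param config run configuration (see \code{\link{validateRunConfig}});
#'   a partial list of overrides is accepted.
#' @param seed integer master seed; stage seeds are derived from it.
#' @param outDir optional directory: results are written as JSON/CSV with an
#'   md5 manifest.
#' @param verbose print stage progress?
#' @return list with elements \code{data} (the simulated dataset),
#'   \code{maps}, \code{clusterResult}, \code{components},
#'   \code{trialTable}, \code{icc}, \code{classification},
#'   \code{associations}, \code{groupTests}, \code{retention},
#'   \code{config} and \code{seed}.
#' @export
runPipeline <- function(config = list(), seed = 1, outDir = NULL,
                        verbose = TRUE) {
  cfg <- validateRunConfig(config)
  say <- function(...) if (verbose) message(sprintf(...))

  set.seed(seed)
  stageSeeds <- sample.int(.Machine$integer.max, 4L)

  say("simulating %d participants ...", cfg$nPd + cfg$nControl)
  sim <- simulationConfig(
    nPd = cfg$nPd, nControl = cfg$nControl,
    nOdorTrials = cfg$nOdorTrials, nSniffTrials = cfg$nSniffTrials,
    fs = cfg$fs, epochWindow = cfg$epochWindow,
    burstSpecs = defaultBurstSpecs(cfg$burstAmp),
    artifactRates = cfg$artifactRates
  )
  data <- generateDataset(sim, seed = stageSeeds[1L])

  say("preprocessing and time-frequency contrasts ...")
  epochDur <- diff(cfg$epochWindow) - cfg$delay
  plan <- planTapers(cfg$freqs, cfg$fs, epochDur)
  maps <- vector("list", length(data$epochs))
  trialMaps <- vector("list", length(data$epochs))
  retention <- numeric(length(data$epochs))
  names(maps) <- names(trialMaps) <- names(retention) <- names(data$epochs)
  for (s in seq_along(data$epochs)) {
    pre <- preprocessSubject(
      data$epochs[[s]],
      notch = cfg$notch, delay = cfg$delay,
      muscleZ = cfg$muscleZ, blinkZ = cfg$blinkZ
    )
    retention[s] <- attr(pre, "retention")
    res <- subjectContrastMap(
      pre, cfg$freqs, cfg$times,
      baselineWindow = cfg$baselineWindow, returnTrials = TRUE, plan = plan
    )
    maps[[s]] <- res$map
    trialMaps[[s]] <- res$trialMaps
  }
  groups <- data$truth$groups
  subjects <- data$truth$subjects

  say("cluster permutation test (%d permutations) ...", cfg$nPerm)
  clusterResult <- permutationTest(
    maps, groups,
    nPerm = cfg$nPerm, alphaBin = cfg$alphaBin, minSize = cfg$minSize,
    alphaCluster = cfg$alphaCluster, seed = stageSeeds[2L]
  )

  components <- extractComponents(clusterResult)
  k <- nComponents(components)
  say("%d component(s) retained", k)

  trialTable <- NULL
  icc <- list()
  classification <- NULL
  associations <- NULL
  groupTests <- NULL
  if (k > 0L) {
    components <- scoreSubjects(components, maps, trialMaps, subjects, groups)
    trialTable <- trialScoreTable(components, z = TRUE)
    compCols <- paste0("comp", seq_len(k))

    say("trial-split reliability ...")
    for (j in seq_len(k)) {
      for (g in unique(groups)) {
        key <- sprintf("%s.%s", compCols[j], g)
        icc[[key]] <- tryCatch(
          icc2k(iccSplitScores(
            components, j,
            nSplits = cfg$nSplits,
            seed = stageSeeds[3L], subjects = subjects[groups == g]
          ))$icc2k,
          error = function(e) NA_real_
        )
      }
    }

    say("classification ...")
    step <- stepwiseSelect(trialTable, compCols)
    fullFit <- step$fits[[length(step$fits)]]
    bestFit <- step$fits[[step$bestStep]]
    fits <- setNames(step$fits, vapply(step$fits, function(f) {
      paste(f$predictors, collapse = "+")
    }, character(1L)))
    classification <- list(
      stepwise = step, fit = bestFit, aic = aicCompare(fits),
      confusion = confusionReport(bestFit),
      fullConfusion = confusionReport(fullFit)
    )

    say("clinical associations ...")
    associations <- list(
      table = associate(trialTable, data$clinical, cfg$outcome),
      bootstrap = bootstrapAssociations(
        trialTable, data$clinical, cfg$outcome,
        component = "comp1", nBoot = cfg$nBoot, seed = stageSeeds[4L]
      )
    )

    groupTests <- lapply(seq_len(k), function(j) {
      sc <- componentScores(components)[, j]
      groupTtest(sc[groups == "Control"], sc[groups == "PD"])
    })
    names(groupTests) <- compCols
  }

  hypo <- classifyHyposmia(data$clinical$odor_id)
  hyposmiaRate <- tapply(hypo == "hyposmic", data$clinical$group, mean)

  out <- list(
    data = data, maps = maps, clusterResult = clusterResult,
    components = components, trialTable = trialTable, icc = icc,
    classification = classification, associations = associations,
    groupTests = groupTests, hyposmiaRate = as.list(hyposmiaRate),
    retention = retention, config = cfg, seed = seed
  )
  if (!is.null(outDir)) writePipelineOutputs(out, outDir)
  out
}

#' Write pipeline outputs to disk
#'
#' Writes \code{clinical.csv}, \code{subject_scores.csv},
#' \code{trial_scores.csv}, a \code{results.json} summary and a
#' \code{manifest.json} with md5 checksums of every written file.
#'
#' @param result a \code{\link{runPipeline}} result.
#' @param outDir output directory (created if absent).
#' @return invisibly, the manifest as a named list of md5 strings.
#' @export
writePipelineOutputs <- function(result, outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  files <- character()

  f <- file.path(outDir, "clinical.csv")
  write.csv(result$data$clinical, f, row.names = FALSE)
  files <- c(files, f)

  comps <- result$components
  if (nComponents(comps) > 0L && !is.null(componentScores(comps))) {
    f <- file.path(outDir, "subject_scores.csv")
    sc <- data.frame(
      subject = comps@subjects, group = comps@groups,
      componentScores(comps), check.names = FALSE
    )
    write.csv(sc, f, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(result$trialTable)) {
    f <- file.path(outDir, "trial_scores.csv")
    write.csv(result$trialTable, f, row.names = FALSE)
    files <- c(files, f)
  }

  cr <- result$clusterResult
  summary <- list(
    seed = result$seed,
    nSubjects = length(result$maps),
    retention = as.list(result$retention),
    nClusters = length(cr@clusters),
    nRetained = nRetained(cr),
    clusters = lapply(cr@clusters, function(cl) {
      list(
        size = cl$size, mass = cl$mass, sign = cl$sign,
        onsetTime = cl$onsetTime, minFreq = cl$minFreq, p = cl$pPerm
      )
    }),
    icc = result$icc,
    hyposmiaRate = result$hyposmiaRate
  )
  if (!is.null(result$classification)) {
    summary$classification <- list(
      selected = result$classification$stepwise$selected,
      path = result$classification$stepwise$path,
      confusion = result$classification$confusion
    )
  }
  if (!is.null(result$associations)) {
    summary$associations <- list(
      table = result$associations$table,
      bootstrapP = result$associations$bootstrap$p
    )
  }
  f <- file.path(outDir, "results.json")
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA, pretty = TRUE), f)
  files <- c(files, f)

  manifest <- as.list(tools::md5sum(files))
  names(manifest) <- basename(files)
  writeLines(
    jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
    file.path(outDir, "manifest.json")
  )
  invisible(manifest)
}
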