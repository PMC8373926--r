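## Synthetic study generator.
##
## Emulates the recording and cohort structure the analysis assumes: two
## groups (20 patients / 18 controls by default), 72 odor + 24 sniff epochs
## per participant at 512 Hz on four EBG channels plus mastoid and vertical
## EOG references, 1/f + white background noise, coherent 50 Hz line noise,
## group-differential Gabor bursts (Gaussian-windowed cosines), blink/muscle
## artifacts, and Table-1-style clinical covariates.  Every stochastic
## element is driven by a single integer seed; identical (config, seed) gives
## bit-identical output.

#' Default burst specifications
#'
#' Six group-differential oscillatory bursts matching the time-frequency
#' components the analysis is designed to detect: control-dominant bursts in
#' the gamma band near 460 ms, beta near 620 ms and theta near 680 ms after
#' odor onset, and patient-dominant bursts in gamma near 660 ms and 980 ms
#' and alpha/beta near odor onset.  Amplitudes (microvolts, peak) are
#' calibrated for testability -- they give a subject-level effect size of
#' roughly d = 2.5-3 on the resulting contrast-map scores under the default
#' noise model -- not to match any empirical effect size.
#'
#' @param amp peak amplitude (microvolts) given to the dominant group.
#' @return data.frame with one row per burst.
#' @export
defaultBurstSpecs <- function(amp = 8) {
  data.frame(
    label = paste0("burst", 1:6),
    freq = c(12, 65, 20, 6, 65, 65),
    time = c(0.02, 0.46, 0.62, 0.68, 0.66, 0.98),
    freqSd = c(1, 2, 1, 0.5, 2, 2),
    timeSd = c(0.05, 0.04, 0.05, 0.06, 0.04, 0.05),
    ampControl = c(0, amp, amp, amp, 0, 0),
    ampPd = c(amp, 0, 0, 0, amp, amp),
    phaseLockedFraction = 0,
    condition = "odor",
    stringsAsFactors = FALSE
  )
}

#' Construct a SimulationConfig
#'
#' All arguments default to the emulated study's conditions; see
#' \code{\linkS4class{SimulationConfig}}.
#'
#' @param nPd,nControl group sizes.
#' @param nOdorTrials,nSniffTrials trials per participant.
#' @param fs sampling rate, Hz.
#' @param epochWindow c(t0, t1) in seconds.
#' @param channels channel labels (EBG1-4, M1, M2, EOGL, EOGR).
#' @param burstSpecs burst data.frame; see \code{\link{defaultBurstSpecs}}.
#' @param ampSubjectSd between-subject amplitude SD (microvolts).
#' @param artifactRates named c(blink=, muscle=) events per epoch.
#' @param lineNoiseAmp 50 Hz line amplitude (microvolts).
#' @param noiseExponent,noiseSd,noiseFloorSd background-noise model.
#' @param covariateCoupling list of list(outcome=, burst=, rho=) couplings.
#' @return a \code{\linkS4class{SimulationConfig}}.
#' @export
simulationConfig <- function(nPd = 20, nControl = 18, nOdorTrials = 72,
                             nSniffTrials = 24, fs = 512,
                             epochWindow = c(-2, 2),
                             channels = c(
                               "EBG1", "EBG2", "EBG3", "EBG4",
                               "M1", "M2", "EOGL", "EOGR"
                             ),
                             burstSpecs = defaultBurstSpecs(),
                             ampSubjectSd = 1,
                             artifactRates = c(blink = 0.05, muscle = 0.05),
                             lineNoiseAmp = 2, noiseExponent = 1,
                             noiseSd = 10, noiseFloorSd = 1,
                             covariateCoupling = list()) {
  new("SimulationConfig",
    nPd = nPd, nControl = nControl, nOdorTrials = nOdorTrials,
    nSniffTrials = nSniffTrials, fs = fs, epochWindow = epochWindow,
    channels = channels, burstSpecs = burstSpecs,
    ampSubjectSd = ampSubjectSd, artifactRates = artifactRates,
    lineNoiseAmp = lineNoiseAmp, noiseExponent = noiseExponent,
    noiseSd = noiseSd, noiseFloorSd = noiseFloorSd,
    covariateCoupling = covariateCoupling
  )
}

## epoch sample count: half-open convention, N = round(fs * duration)
epochSamples <- function(config) {
  as.integer(roundHalfUp(config@fs * diff(config@epochWindow)))
}

#' Generate a complete synthetic dataset
#'
#' Draws per-participant epochs (background noise + line noise + injected
#' bursts + optional artifacts) and clinical covariates, and records the
#' ground truth needed to validate every downstream stage.
#'
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @param seed integer seed; identical (config, seed) gives bit-identical
#'   output.
#' @return list with elements \code{epochs} (list of
#'   \code{\linkS4class{EpochSet}}, one per participant), \code{clinical}
#'   (data.frame, one row per participant) and \code{truth} (list with the
#'   burst table, the subject x burst amplitude matrix, per-subject artifact
#'   labels, and the covariate coupling used).
#' @export
generateDataset <- function(config, seed = 1) {
  validObject(config)
  set.seed(seed)
  n <- epochSamples(config)
  times <- config@epochWindow[1L] + (seq_len(n) - 1L) / config@fs
  nCh <- length(config@channels)
  nTr <- config@nOdorTrials + config@nSniffTrials
  condition <- c(rep("odor", config@nOdorTrials), rep("sniff", config@nSniffTrials))
  ids <- c(
    sprintf("PD%02d", seq_len(config@nPd)),
    sprintf("C%02d", seq_len(config@nControl))
  )
  groups <- c(rep("PD", config@nPd), rep("Control", config@nControl))
  bs <- config@burstSpecs
  nB <- nrow(bs)
  ebg <- ebgChannels(config@channels)

  ## per-subject burst amplitudes (truncated at zero)
  subjectAmps <- matrix(0, length(ids), max(nB, 1L),
    dimnames = list(ids, if (nB) bs$label else NULL)
  )
  if (nB) {
    for (b in seq_len(nB)) {
      base <- ifelse(groups == "PD", bs$ampPd[b], bs$ampControl[b])
      subjectAmps[, b] <- pmax(0, base + rnorm(length(ids), 0, config@ampSubjectSd))
    }
  }

  artifactSeeds <- sample.int(.Machine$integer.max, length(ids))
  covSeed <- sample.int(.Machine$integer.max, 1L)

  epochs <- vector("list", length(ids))
  names(epochs) <- ids
  artifactTruth <- vector("list", length(ids))
  names(artifactTruth) <- ids

  for (s in seq_along(ids)) {
    dat <- array(0, c(nTr, nCh, n))
    for (tr in seq_len(nTr)) {
      for (ch in seq_len(nCh)) {
        dat[tr, ch, ] <- config@noiseSd * oneOverFNoise(n, config@fs, config@noiseExponent) +
          config@noiseFloorSd * rnorm(n)
      }
    }
    if (config@lineNoiseAmp > 0) {
      for (ch in seq_len(nCh)) {
        phi <- runif(1, 0, 2 * pi)
        line <- config@lineNoiseAmp * sin(2 * pi * 50 * times + phi)
        for (tr in seq_len(nTr)) dat[tr, ch, ] <- dat[tr, ch, ] + line
      }
    }
    if (nB) {
      for (b in seq_len(nB)) {
        amp <- subjectAmps[s, b]
        if (amp <= 0) next
        trIdx <- if (bs$condition[b] == "both") {
          seq_len(nTr)
        } else {
          which(condition == bs$condition[b])
        }
        for (tr in trIdx) {
          phi <- if (runif(1) < bs$phaseLockedFraction[b]) 0 else runif(1, 0, 2 * pi)
          f <- bs$freq[b] + rnorm(1, 0, bs$freqSd[b])
          burst <- amp * exp(-(times - bs$time[b])^2 / (2 * bs$timeSd[b]^2)) *
            cos(2 * pi * f * (times - bs$time[b]) + phi)
          for (ch in ebg) dat[tr, ch, ] <- dat[tr, ch, ] + burst
        }
      }
    }
    es <- epochSet(dat, config@fs,
      times = times, channels = config@channels,
      condition = condition, subject = ids[s], group = groups[s]
    )
    if (any(config@artifactRates > 0)) {
      inj <- injectArtifacts(es, config@artifactRates, seed = artifactSeeds[s])
      es <- inj$epochs
      artifactTruth[[s]] <- inj$labels
    } else {
      artifactTruth[[s]] <- data.frame(
        trial = integer(), type = character(), time = numeric()
      )
    }
    epochs[[s]] <- es
  }

  clinical <- generateCovariates(config, subjectAmps, seed = covSeed)

  list(
    epochs = epochs,
    clinical = clinical,
    truth = list(
      bursts = bs, subjectAmps = subjectAmps, groups = groups,
      subjects = ids, artifacts = artifactTruth,
      coupling = config@covariateCoupling
    )
  )
}

#' Inject blink and muscle artifacts into an EpochSet
#'
#' Blink events are biphasic low-frequency (derivative-of-Gaussian, sigma =
#' 0.15 s) deflections, full amplitude on the EOG channels and attenuated
#' (x 0.3) on the EBG channels.  Muscle events are Gaussian-windowed
#' high-frequency (20-45 Hz band) noise bursts on the EBG channels.  Event
#' counts per epoch are Poisson with the configured rates.
#'
#' @param epochs an \code{\linkS4class{EpochSet}}.
#' @param rates named numeric \code{c(blink=, muscle=)}: expected events per
#'   epoch.
#' @param seed integer seed.
#' @param ampBlink,ampMuscle peak amplitudes in microvolts.
#' @return list(epochs = modified EpochSet, labels = data.frame(trial, type,
#'   time)).  With both rates zero the epochs are returned unchanged and the
#'   label table is empty.
#' @export
injectArtifacts <- function(epochs, rates = c(blink = 0.05, muscle = 0.05),
                            seed = 1, ampBlink = 150, ampMuscle = 80) {
  stopifnot(is(epochs, "EpochSet"))
  if (!all(c("blink", "muscle") %in% names(rates))) {
    stop("rates must have 'blink' and 'muscle' entries")
  }
  labels <- data.frame(trial = integer(), type = character(), time = numeric())
  if (all(rates <= 0)) {
    return(list(epochs = epochs, labels = labels))
  }
  set.seed(seed)
  dat <- epochs@data
  times <- epochs@times
  fs <- epochs@fs
  eog <- grep("^EOG", epochs@channels)
  ebg <- ebgChannels(epochs@channels)
  margin <- 0.3
  tLo <- times[1L] + margin
  tHi <- times[length(times)] - margin
  for (tr in seq_len(nTrials(epochs))) {
    nBlink <- rpois(1, rates[["blink"]])
    for (k in seq_len(nBlink)) {
      tc <- runif(1, tLo, tHi)
      shape <- -(times - tc) / 0.15 * exp(0.5 - (times - tc)^2 / (2 * 0.15^2))
      for (ch in eog) dat[tr, ch, ] <- dat[tr, ch, ] + ampBlink * shape
      for (ch in ebg) dat[tr, ch, ] <- dat[tr, ch, ] + 0.3 * ampBlink * shape
      labels <- rbind(labels, data.frame(trial = tr, type = "blink", time = tc))
    }
    nMus <- rpois(1, rates[["muscle"]])
    for (k in seq_len(nMus)) {
      tc <- runif(1, tLo, tHi)
      env <- exp(-(times - tc)^2 / (2 * 0.08^2))
      hi <- min(45, 0.45 * fs)
      carrier <- bandpassFilter(rnorm(length(times)), c(20, hi), fs)
      carrier <- carrier / max(sd(carrier), 1e-12)
      for (ch in ebg) dat[tr, ch, ] <- dat[tr, ch, ] + ampMuscle * env * carrier
      labels <- rbind(labels, data.frame(trial = tr, type = "muscle", time = tc))
    }
  }
  out <- epochs
  out@data <- dat
  list(epochs = out, labels = labels)
}

#' Generate clinical covariates for a synthetic cohort
#'
#' Covariates are drawn from truncated-normal / discretized distributions
#' matching the emulated cohort: age about 62 +/- 9 years in both groups,
#' patient disease duration 3.95 +/- 2.19 years, levodopa-equivalent daily
#' dose 526 +/- 355 mg, Hoehn & Yahr stage 1.65 +/- 0.67 (snapped to half
#' stages in [1, 3]), MoCA 26.9 +/- 4.5, and 16-item odor identification
#' scores of 7.3 +/- 3.36 (patients) and 13.78 +/- 1.26 (controls), clipped
#' to [0, 16].  Couplings listed in the config tie a covariate to a burst's
#' per-subject amplitude with correlation \code{rho} while preserving the
#' marginal mean and SD.
#'
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @param subjectAmps subject x burst amplitude matrix (from
#'   \code{\link{generateDataset}}'s ground truth).
#' @param seed integer seed.
#' @return data.frame with columns id, group, age, sex, ledd, duration, hy,
#'   moca, odor_id (PD-only fields are NA for controls and absent entirely if
#'   the cohort has no patients).
#' @export
generateCovariates <- function(config, subjectAmps = NULL, seed = 1) {
  set.seed(seed)
  ids <- c(
    sprintf("PD%02d", seq_len(config@nPd)),
    sprintf("C%02d", seq_len(config@nControl))
  )
  groups <- c(rep("PD", config@nPd), rep("Control", config@nControl))
  nAll <- length(ids)
  isPd <- groups == "PD"

  coupleDraw <- function(outcome, n, which, mu, sdv) {
    ## standard normal deviate, optionally correlated with a burst amplitude
    z <- rnorm(n)
    for (cp in config@covariateCoupling) {
      if (identical(cp$outcome, outcome) && !is.null(subjectAmps) &&
        cp$burst <= ncol(subjectAmps)) {
        a <- subjectAmps[which, cp$burst]
        if (sd(a) > 0) {
          za <- (a - mean(a)) / sd(a)
          z <- cp$rho * za + sqrt(1 - cp$rho^2) * z
        }
      }
    }
    mu + sdv * z
  }

  age <- numeric(nAll)
  age[isPd] <- pmin(pmax(rnorm(sum(isPd), 61.92, 9.01), 46), 75)
  age[!isPd] <- pmin(pmax(rnorm(sum(!isPd), 61.82, 8.80), 41), 74)
  sex <- ifelse(runif(nAll) < 0.2, "F", "M")

  ledd <- duration <- hy <- moca <- rep(NA_real_, nAll)
  if (any(isPd)) {
    w <- which(isPd)
    ledd[w] <- pmax(coupleDraw("ledd", length(w), w, 526, 355), 0)
    duration[w] <- pmax(coupleDraw("duration", length(w), w, 3.95, 2.19), 0.1)
    hyRaw <- coupleDraw("hy", length(w), w, 1.65, 0.67)
    hy[w] <- pmin(pmax(roundHalfUp(hyRaw * 2) / 2, 1), 3)
    moca[w] <- pmin(pmax(roundHalfUp(coupleDraw("moca", length(w), w, 26.89, 4.46)), 0), 30)
  }
  odor <- numeric(nAll)
  if (any(isPd)) {
    w <- which(isPd)
    odor[w] <- coupleDraw("odor_id", length(w), w, 7.3, 3.36)
  }
  if (any(!isPd)) {
    w <- which(!isPd)
    odor[w] <- coupleDraw("odor_id", length(w), w, 13.78, 1.26)
  }
  odor <- pmin(pmax(roundHalfUp(odor), 0), 16)

  out <- data.frame(
    id = ids, group = groups, age = age, sex = sex,
    ledd = ledd, duration = duration, hy = hy, moca = moca,
    odor_id = as.integer(odor), stringsAsFactors = FALSE
  )
  if (!any(isPd)) out <- out[, c("id", "group", "age", "sex", "odor_id")]
  out
}

#' Simulate component trial scores for classifier validation
#'
#' Score-level generator for the model stage: one informative component whose
#' subject-level group separation is \code{d} (in subject SD units) plus
#' \code{nNoise} uninformative components, each observed on \code{nTrials}
#' noisy trials per subject.
#'
#' @param nPd,nControl group sizes.
#' @param nTrials trials per subject.
#' @param d subject-level standardized group difference of the informative
#'   component (Control minus PD).
#' @param trialSd within-subject trial noise SD.
#' @param nNoise number of pure-noise components.
#' @param seed integer seed.
#' @return long data.frame with columns subject, group, comp1 (informative),
#'   comp2..comp(nNoise+1).
#' @export
simulateComponentScores <- function(nPd = 20, nControl = 18, nTrials = 20,
                                    d = 1.5, trialSd = 1, nNoise = 3,
                                    seed = 1) {
  set.seed(seed)
  ids <- c(sprintf("PD%02d", seq_len(nPd)), sprintf("C%02d", seq_len(nControl)))
  groups <- c(rep("PD", nPd), rep("Control", nControl))
  nSub <- length(ids)
  means <- cbind(
    rnorm(nSub, ifelse(groups == "Control", d, 0), 1),
    matrix(rnorm(nSub * nNoise), nSub, nNoise)
  )
  rows <- rep(seq_len(nSub), each = nTrials)
  scores <- means[rows, , drop = FALSE] +
    matrix(rnorm(length(rows) * ncol(means), 0, trialSd), length(rows))
  colnames(scores) <- paste0("comp", seq_len(ncol(scores)))
  data.frame(
    subject = ids[rows], group = groups[rows], scores,
    stringsAsFactors = FALSE
  )
}

#' Simulate trial scores coupled to a clinical outcome
#'
#' Score-level generator for association validation: subject-level component
#' scores correlated \code{rho} with a continuous outcome, observed on noisy
#' trials.  The default \code{rho = 0.6} gives roughly 80\% power at n = 20
#' subjects.
#'
#' @param nSubjects number of subjects.
#' @param nTrials trials per subject.
#' @param rho subject-level correlation between score and outcome.
#' @param trialSd within-subject trial noise SD.
#' @param seed integer seed.
#' @return list(trialScores = data.frame(subject, score), clinical =
#'   data.frame(subject, outcome)).
#' @export
simulateAssociationScores <- function(nSubjects = 20, nTrials = 20, rho = 0.6,
                                      trialSd = 0.5, seed = 1) {
  set.seed(seed)
  ids <- sprintf("S%02d", seq_len(nSubjects))
  m <- rnorm(nSubjects)
  zm <- (m - mean(m)) / sd(m)
  outcome <- rho * zm + sqrt(max(0, 1 - rho^2)) * rnorm(nSubjects)
  rows <- rep(seq_len(nSubjects), each = nTrials)
  list(
    trialScores = data.frame(
      subject = ids[rows],
      score = m[rows] + rnorm(length(rows), 0, trialSd),
      stringsAsFactors = FALSE
    ),
    clinical = data.frame(subject = ids, outcome = outcome, stringsAsFactors = FALSE)
  )
}
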