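## Core S4 containers.
##
## Conventions used everywhere in the package:
##  * epochs hold N = round(fs * (t1 - t0)) samples, half-open time axis
##    t = t0 + k/fs for k = 0..N-1 (both stated once here, used everywhere);
##  * channel order is fixed by the `channels` slot; EBG channels are the ones
##    whose label starts with "EBG", mastoids "M1"/"M2", vertical EOG "EOG*";
##  * all signals are in microvolts.

#' EpochSet: epoched multichannel recording
#'
#' Trials x channels x samples array time-locked to stimulus onset, with the
#' per-trial condition (\code{"odor"} or \code{"sniff"}), artifact flags
#' (\code{"clean"}, \code{"blink"} or \code{"muscle"}), and subject metadata.
#'
#' @slot data numeric array, trials x channels x samples (microvolts).
#' @slot fs sampling rate in Hz.
#' @slot times numeric vector of sample times in seconds relative to
#'   (delay-corrected) stimulus onset; length equals \code{dim(data)[3]}.
#' @slot channels character vector of channel labels, length
#'   \code{dim(data)[2]}.
#' @slot condition character vector per trial, \code{"odor"}/\code{"sniff"}.
#' @slot artifactFlags character vector per trial: \code{"clean"},
#'   \code{"blink"} or \code{"muscle"}.
#' @slot subject subject identifier.
#' @slot group group label (e.g. \code{"Control"} or \code{"PD"}).
#' @export
setClass("EpochSet",
  representation(
    data = "array", fs = "numeric", times = "numeric",
    channels = "character", condition = "character",
    artifactFlags = "character", subject = "character", group = "character"
  )
)

setValidity("EpochSet", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3-d array (trials x channels x samples)")
  if (length(object@times) != d[3L]) return("times length must match sample dimension")
  if (length(object@channels) != d[2L]) return("channels length must match channel dimension")
  if (length(object@condition) != d[1L]) return("condition length must match trial dimension")
  if (length(object@artifactFlags) != d[1L]) return("artifactFlags length must match trial dimension")
  if (object@fs <= 0) return("fs must be positive")
  if (!all(object@artifactFlags %in% c("clean", "blink", "muscle")))
    return("artifactFlags must be 'clean', 'blink' or 'muscle'")
  if (d[3L] >= 2 && any(abs(diff(object@times) - 1 / object@fs) > 1e-6))
    return("times must be a uniform 1/fs grid")
  TRUE
})

#' Construct an EpochSet
#'
#' @param data trials x channels x samples array (microvolts).
#' @param fs sampling rate, Hz.
#' @param times sample time axis (s); defaults to a half-open grid starting at
#'   \code{t0}.
#' @param channels channel labels.
#' @param condition per-trial condition labels (\code{"odor"}/\code{"sniff"}).
#' @param artifactFlags per-trial flags; default all \code{"clean"}.
#' @param subject,group subject id and group label.
#' @param t0 epoch start time (s) used when \code{times} is missing.
#' @return An \code{\linkS4class{EpochSet}}.
#' @export
epochSet <- function(data, fs, times = NULL, channels = NULL,
                     condition = NULL, artifactFlags = NULL,
                     subject = "s1", group = "Control", t0 = -2) {
  d <- dim(data)
  if (is.null(times)) times <- t0 + (seq_len(d[3L]) - 1L) / fs
  if (is.null(channels)) channels <- paste0("ch", seq_len(d[2L]))
  if (is.null(condition)) condition <- rep("odor", d[1L])
  if (is.null(artifactFlags)) artifactFlags <- rep("clean", d[1L])
  new("EpochSet",
    data = data, fs = fs, times = times, channels = channels,
    condition = condition, artifactFlags = artifactFlags,
    subject = as.character(subject), group = as.character(group)
  )
}

#' @describeIn epochSet number of trials.
#' @param x an \code{EpochSet}.
#' @export
nTrials <- function(x) dim(x@data)[1L]

#' Channel labels of an EpochSet
#' @param x an \code{EpochSet}.
#' @return character vector.
#' @export
channelLabels <- function(x) x@channels

#' Indices of EBG (forehead) channels
#' @param x an \code{EpochSet} or character vector of labels.
#' @return integer vector.
#' @export
ebgChannels <- function(x) {
  labs <- if (is.character(x)) x else x@channels
  grep("^EBG", labs)
}

#' Per-trial artifact flags
#' @param x an \code{EpochSet}.
#' @return character vector, one of \code{"clean"}, \code{"blink"},
#'   \code{"muscle"} per trial.
#' @export
artifactFlags <- function(x) x@artifactFlags

#' Keep only artifact-free trials
#' @param x an \code{EpochSet}.
#' @param condition optional condition to select as well.
#' @return an \code{EpochSet} restricted to clean trials.
#' @export
cleanTrials <- function(x, condition = NULL) {
  keep <- x@artifactFlags == "clean"
  if (!is.null(condition)) keep <- keep & x@condition == condition
  subsetTrials(x, which(keep))
}

subsetTrials <- function(x, idx) {
  new("EpochSet",
    data = x@data[idx, , , drop = FALSE], fs = x@fs, times = x@times,
    channels = x@channels, condition = x@condition[idx],
    artifactFlags = x@artifactFlags[idx], subject = x@subject, group = x@group
  )
}

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "EpochSet: subject %s (%s), %d trials x %d channels x %d samples @ %g Hz\n",
    object@subject, object@group, d[1L], d[2L], d[3L], object@fs
  ))
  cat(sprintf(
    "  window [%.3f, %.3f] s; conditions: %s; clean: %d/%d\n",
    object@times[1L], object@times[length(object@times)],
    paste(sprintf("%s=%d", names(table(object@condition)), table(object@condition)),
      collapse = ", "
    ),
    sum(object@artifactFlags == "clean"), d[1L]
  ))
})

#' TimeFreqMap: a frequency x time power map
#'
#' @slot values numeric matrix, frequencies x times.  Power (arbitrary
#'   microvolt-squared units) or decibels depending on \code{units}.
#' @slot freqs frequency axis, Hz (strictly increasing).
#' @slot times time axis, s (strictly increasing).
#' @slot kind one of \code{"total"}, \code{"evoked"}, \code{"induced"},
#'   \code{"contrast"}.
#' @slot units \code{"power"} or \code{"dB"}.
#' @slot info provenance list (condition, channels averaged, baseline window).
#' @export
setClass("TimeFreqMap",
  representation(
    values = "matrix", freqs = "numeric", times = "numeric",
    kind = "character", units = "character", info = "list"
  )
)

setValidity("TimeFreqMap", function(object) {
  if (nrow(object@values) != length(object@freqs)) {
    return("values must have one row per frequency")
  }
  if (ncol(object@values) != length(object@times)) {
    return("values must have one column per time bin")
  }
  if (any(diff(object@freqs) <= 0) || (length(object@times) > 1 && any(diff(object@times) <= 0))) {
    return("axes must be strictly increasing")
  }
  if (!object@kind %in% c("total", "evoked", "induced", "contrast")) {
    return("kind must be total/evoked/induced/contrast")
  }
  if (!object@units %in% c("power", "dB")) return("units must be 'power' or 'dB'")
  if (object@units == "power" && object@kind %in% c("total", "evoked") &&
    any(object@values < 0, na.rm = TRUE)) {
    return("total/evoked power must be non-negative")
  }
  TRUE
})

#' Construct a TimeFreqMap
#' @param values frequencies x times matrix.
#' @param freqs,times axes (Hz, s).
#' @param kind map kind (\code{"total"}, \code{"evoked"}, \code{"induced"},
#'   \code{"contrast"}).
#' @param units \code{"power"} or \code{"dB"}.
#' @param info provenance list.
#' @return A \code{\linkS4class{TimeFreqMap}}.
#' @export
timeFreqMap <- function(values, freqs, times, kind = "total",
                        units = "power", info = list()) {
  new("TimeFreqMap",
    values = values, freqs = freqs, times = times,
    kind = kind, units = units, info = info
  )
}

#' Extract the value matrix of a TimeFreqMap
#' @param x a \code{TimeFreqMap}.
#' @return numeric matrix, frequencies x times.
#' @export
tfValues <- function(x) x@values

setMethod("show", "TimeFreqMap", function(object) {
  cat(sprintf(
    "TimeFreqMap (%s, %s): %d freqs [%g-%g Hz] x %d times [%g, %g] s; %d NaN bins\n",
    object@kind, object@units, length(object@freqs), min(object@freqs),
    max(object@freqs), length(object@times), min(object@times),
    max(object@times), sum(!is.finite(object@values))
  ))
})

#' ClusterResult: cluster-based permutation test output
#'
#' @slot tMap frequencies x times matrix of two-sample t values (NA where the
#'   map had edge NaNs or zero pooled variance).
#' @slot pMap per-bin two-tailed p values.
#' @slot df degrees of freedom of the per-bin t statistic.
#' @slot clusters list of candidate clusters; each has \code{bins} (indices
#'   into the map matrix), \code{size}, \code{mass} (sum of member t),
#'   \code{sign}, \code{pPerm}, \code{onsetTime}, \code{minFreq} and
#'   \code{peak}.  Retained clusters satisfy \code{pPerm < 0.05} and
#'   \code{size > minSize}.
#' @slot retained logical per cluster.
#' @slot nullMax Monte Carlo null distribution of the maximum absolute cluster
#'   mass.
#' @slot nPerm,seed,alphaBin,minSize test parameters.
#' @slot freqs,times map axes.
#' @export
setClass("ClusterResult",
  representation(
    tMap = "matrix", pMap = "matrix", df = "numeric", clusters = "list",
    retained = "logical", nullMax = "numeric", nPerm = "numeric",
    seed = "numeric", alphaBin = "numeric", minSize = "numeric",
    freqs = "numeric", times = "numeric"
  )
)

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf(
    "ClusterResult: %d candidate clusters (%d retained), %d permutations, df = %d\n",
    length(object@clusters), sum(object@retained), object@nPerm, object@df
  ))
  for (i in seq_along(object@clusters)) {
    cl <- object@clusters[[i]]
    cat(sprintf(
      "  %s cluster: size %d, mass %.1f, p = %.4g, onset %.3f s, peak %.1f Hz / %.3f s%s\n",
      if (cl$sign > 0) "positive" else "negative", cl$size, cl$mass, cl$pPerm,
      cl$onsetTime, cl$peak["freq"], cl$peak["time"],
      if (object@retained[i]) " [retained]" else ""
    ))
  }
})

#' Number of retained clusters
#' @param x a \code{ClusterResult}.
#' @return integer.
#' @export
nRetained <- function(x) sum(x@retained)

#' Retained clusters of a ClusterResult
#' @param x a \code{ClusterResult}.
#' @return list of cluster descriptors.
#' @export
retainedClusters <- function(x) x@clusters[x@retained]

#' ComponentSet: ordered, signed EBG components
#'
#' Retained clusters relabelled by order of appearance (earliest member time
#' bin first; ties broken by lower minimum frequency), with subject and trial
#' scores once \code{\link{scoreSubjects}} has been applied.
#'
#' @slot masks list of logical frequencies x times matrices.
#' @slot labels character labels \code{"Component 1"}, ...
#' @slot signs +1 where the first group of the contrast (e.g. Control)
#'   exceeds the second, else -1.
#' @slot onsets earliest member time (s) per component.
#' @slot peaks data.frame with peak frequency, time and |t| per component.
#' @slot freqs,times map axes.
#' @slot scores subject x component matrix of mean contrast power (dB), or
#'   NULL before scoring.
#' @slot zScores z-scored version of \code{scores} (pooled across groups).
#' @slot trialScores list per subject of trial x component matrices.
#' @slot subjects,groups subject ids and group labels for score rows.
#' @export
setClass("ComponentSet",
  representation(
    masks = "list", labels = "character", signs = "numeric",
    onsets = "numeric", peaks = "data.frame", freqs = "numeric",
    times = "numeric", scores = "ANY", zScores = "ANY",
    trialScores = "list", subjects = "character", groups = "character"
  ),
  prototype(
    scores = NULL, zScores = NULL, trialScores = list(),
    subjects = character(), groups = character()
  )
)

setValidity("ComponentSet", function(object) {
  k <- length(object@masks)
  if (length(object@labels) != k || length(object@signs) != k ||
    length(object@onsets) != k) {
    return("labels, signs and onsets must match the number of masks")
  }
  if (k > 1 && any(diff(object@onsets) < -1e-12)) {
    return("components must be ordered by onset")
  }
  TRUE
})

#' Number of components
#' @param x a \code{ComponentSet}.
#' @return integer.
#' @export
nComponents <- function(x) length(x@masks)

#' Subject-level component scores
#' @param x a \code{ComponentSet} (after \code{\link{scoreSubjects}}).
#' @param z return the z-scored matrix?
#' @return subject x component matrix.
#' @export
componentScores <- function(x, z = FALSE) if (z) x@zScores else x@scores

setMethod("show", "ComponentSet", function(object) {
  cat(sprintf("ComponentSet: %d components\n", length(object@masks)))
  for (i in seq_along(object@masks)) {
    cat(sprintf(
      "  %s: sign %+d, onset %.3f s, size %d, peak %.1f Hz / %.3f s\n",
      object@labels[i], object@signs[i], object@onsets[i],
      sum(object@masks[[i]]), object@peaks$freq[i], object@peaks$time[i]
    ))
  }
  if (!is.null(object@scores)) {
    cat(sprintf("  scored for %d subjects\n", nrow(object@scores)))
  }
})

#' SimulationConfig: synthetic EBG study configuration
#'
#' Defaults reproduce the recording and cohort structure of the emulated
#' study: 20 patients + 18 controls, 72 odor + 24 sniff trials per
#' participant, 512 Hz sampling, epochs from -2 to +2 s, four EBG channels
#' plus two mastoids and two vertical EOG channels, 1/f background noise with
#' a white floor, 50 Hz line noise, and six group-differential oscillatory
#' bursts (see \code{\link{defaultBurstSpecs}}).
#'
#' @slot nPd,nControl group sizes.
#' @slot nOdorTrials,nSniffTrials trials per participant and condition.
#' @slot fs sampling rate, Hz.
#' @slot epochWindow c(t0, t1) seconds around stimulus onset.
#' @slot channels ordered channel labels.
#' @slot burstSpecs data.frame of burst specifications (one row per burst):
#'   \code{freq} (Hz), \code{time} (s), \code{freqSd} (Hz, per-trial carrier
#'   jitter), \code{timeSd} (s, Gaussian envelope SD), \code{ampControl},
#'   \code{ampPd} (microvolt peak amplitudes), \code{phaseLockedFraction},
#'   \code{condition} (\code{"odor"}, \code{"sniff"} or \code{"both"}).
#' @slot ampSubjectSd between-subject SD of burst amplitude (microvolts).
#' @slot artifactRates named numeric: expected \code{blink} and \code{muscle}
#'   events per epoch.
#' @slot lineNoiseAmp 50 Hz line-noise amplitude, microvolts.
#' @slot noiseExponent spectral exponent chi of the 1/f^chi background.
#' @slot noiseSd RMS of the 1/f background, microvolts.
#' @slot noiseFloorSd RMS of the additive white floor, microvolts.
#' @slot covariateCoupling list of couplings between injected per-subject
#'   burst amplitudes and clinical covariates; each element is
#'   \code{list(outcome=, burst=, rho=)}.
#' @export
setClass("SimulationConfig",
  representation(
    nPd = "numeric", nControl = "numeric", nOdorTrials = "numeric",
    nSniffTrials = "numeric", fs = "numeric", epochWindow = "numeric",
    channels = "character", burstSpecs = "data.frame",
    ampSubjectSd = "numeric", artifactRates = "numeric",
    lineNoiseAmp = "numeric", noiseExponent = "numeric", noiseSd = "numeric",
    noiseFloorSd = "numeric", covariateCoupling = "list"
  )
)

setValidity("SimulationConfig", function(object) {
  if (object@nOdorTrials <= 0 || object@nSniffTrials <= 0) {
    return("trial counts must be positive")
  }
  if (!(object@epochWindow[1L] < 0 && 0 < object@epochWindow[2L])) {
    return("epochWindow must straddle 0")
  }
  if (object@fs <= 0) return("fs must be positive")
  bs <- object@burstSpecs
  if (nrow(bs)) {
    if (any(bs$freq <= 0 | bs$freq >= object@fs / 2)) {
      return("burst frequencies must lie in (0, fs/2)")
    }
    if (any(bs$phaseLockedFraction < 0 | bs$phaseLockedFraction > 1)) {
      return("phaseLockedFraction must lie in [0, 1]")
    }
    if (any(bs$time < object@epochWindow[1L] | bs$time > object@epochWindow[2L])) {
      return("burst centre times must lie inside the epoch window")
    }
    if (!all(bs$condition %in% c("odor", "sniff", "both"))) {
      return("burst condition must be odor/sniff/both")
    }
  }
  if (!all(c("blink", "muscle") %in% names(object@artifactRates))) {
    return("artifactRates must have 'blink' and 'muscle' entries")
  }
  if (any(object@artifactRates < 0)) return("artifactRates must be >= 0")
  TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    paste0(
      "SimulationConfig: %d PD + %d Control; %d odor + %d sniff trials; ",
      "%g Hz, window [%g, %g] s\n  %d channels; %d burst specs; ",
      "artifact rates blink %.3g / muscle %.3g per epoch\n"
    ),
    object@nPd, object@nControl, object@nOdorTrials, object@nSniffTrials,
    object@fs, object@epochWindow[1L], object@epochWindow[2L],
    length(object@channels), nrow(object@burstSpecs),
    object@artifactRates[["blink"]], object@artifactRates[["muscle"]]
  ))
})
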