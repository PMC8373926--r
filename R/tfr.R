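## Frequency-adaptive multitaper time-frequency decomposition.
##
## At each analysis frequency f the signal is windowed (length T(f), at least
## two cycles of f, capped at the epoch length), multiplied by K DPSS tapers
## with half-bandwidth W(f) = 0.8 f, Fourier-transformed at f, and the
## squared magnitudes averaged over tapers.  With T = 2/f and W = 0.8 f the
## time-bandwidth product is TW = 1.6 and K = floor(2TW - 1) = 2 tapers at
## every frequency.  Window centres snap to the nearest sample
## (round-half-up); bins whose window exceeds the epoch support are NaN.

#' Full analysis grid
#'
#' The default analysis grid: frequencies 0.5 to 100 Hz in steps of 0.5 Hz
#' (200 bins) and times -2 to 2 s in steps of 0.01 s (401 bins).
#'
#' @return list(freqs=, times=).
#' @export
fullTfrGrid <- function() {
  list(freqs = seq(0.5, 100, by = 0.5), times = seq(-2, 2, by = 0.01))
}

#' Frequency-adaptive taper plan
#'
#' For each analysis frequency: window length T(f) = min(2/f, epoch
#' duration) seconds (at least two cycles), half-bandwidth W(f) = 0.8 f Hz,
#' and K(f) = max(1, floor(2 T W - 1)) DPSS tapers -- K = 2 everywhere the
#' two-cycle window fits.
#'
#' @param freqs analysis frequencies, Hz.
#' @param fs sampling rate, Hz.
#' @param epochDuration epoch length in seconds (caps the window).
#' @return data.frame with columns freq, T, W, K, L (window length in
#'   samples, odd) and nw (effective time-bandwidth product).
#' @export
planTapers <- function(freqs, fs, epochDuration) {
  if (any(freqs <= 0) || any(freqs >= fs / 2)) {
    stop("analysis frequencies must lie in (0, fs/2)")
  }
  Tw <- pmin(2 / freqs, epochDuration)
  W <- 0.8 * freqs
  K <- pmax(1L, floor(2 * Tw * W - 1 + 1e-9))
  L <- pmin(roundHalfUp(Tw * fs), floor(epochDuration * fs))
  L <- ifelse(L %% 2 == 0, L - 1L, L)
  L <- pmax(L, 3L)
  nw <- (L / fs) * W
  data.frame(freq = freqs, T = Tw, W = W, K = as.integer(K), L = as.integer(L), nw = nw)
}

## Core engine: rows of M are independent signals (nRow x nSamples).
## Returns nRow x nFreq x nTime power array, NaN where the window does not
## fit.  For each frequency a sparse-banded kernel matrix (samples x
## (validTimes * K)) holding taper * exp(-2 pi i f t) is assembled once and
## applied to all rows with two real matrix products.
mtPower <- function(M, fs, times, freqs, outTimes, plan = NULL) {
  N <- ncol(M)
  nRow <- nrow(M)
  if (is.null(plan)) plan <- planTapers(freqs, fs, N / fs)
  out <- array(NA_real_, c(nRow, length(freqs), length(outTimes)))
  centersAll <- as.integer(roundHalfUp((outTimes - times[1L]) * fs)) + 1L
  for (fi in seq_along(freqs)) {
    L <- plan$L[fi]
    K <- plan$K[fi]
    if (L > N) next
    tap <- dpssTapers(L, plan$nw[fi], K)
    h <- (L - 1L) %/% 2L
    relT <- ((0:(L - 1L)) - h) / fs
    phase <- exp(-2i * pi * freqs[fi] * relT)
    wRe <- tap * Re(phase)
    wIm <- tap * Im(phase)
    valid <- which(centersAll - h >= 1L & centersAll + h <= N)
    if (!length(valid)) next
    Kre <- matrix(0, N, length(valid) * K)
    Kim <- matrix(0, N, length(valid) * K)
    for (j in seq_along(valid)) {
      rows <- (centersAll[valid[j]] - h):(centersAll[valid[j]] + h)
      cols <- (j - 1L) * K + seq_len(K)
      Kre[rows, cols] <- wRe
      Kim[rows, cols] <- wIm
    }
    P <- (M %*% Kre)^2 + (M %*% Kim)^2
    dim(P) <- c(nRow, K, length(valid))
    avg <- P[, 1L, ]
    if (K > 1L) {
      for (k in 2:K) avg <- avg + P[, k, ]
      avg <- avg / K
    }
    out[, fi, valid] <- avg
  }
  out
}

#' Per-trial multitaper spectrograms
#'
#' @param epochs an \code{\linkS4class{EpochSet}} (all trials are used; the
#'   caller subsets with \code{\link{cleanTrials}} first).
#' @param freqs,times analysis axes (Hz, s); times must lie on the epoch's
#'   sample grid (centres snap to the nearest sample).
#' @param channels channel indices or labels; default the EBG channels.
#' @param plan optional precomputed \code{\link{planTapers}} result.
#' @return numeric array trials x channels x freqs x times of power
#'   (arbitrary microvolt-squared units); NaN at bins whose window exceeds
#'   the epoch.
#' @export
multitaperTfr <- function(epochs, freqs, times, channels = NULL, plan = NULL) {
  if (is.null(channels)) channels <- ebgChannels(epochs)
  if (is.character(channels)) channels <- match(channels, epochs@channels)
  d <- dim(epochs@data)
  nt <- d[1L]
  nch <- length(channels)
  M <- matrix(epochs@data[, channels, , drop = FALSE], nrow = nt * nch)
  P <- mtPower(M, epochs@fs, epochs@times, freqs, times, plan)
  array(P, c(nt, nch, length(freqs), length(times)))
}

#' Evoked (phase-locked) spectrogram
#'
#' Multitaper power of the trial-average waveform; only phase-consistent
#' activity survives the averaging.
#'
#' @inheritParams multitaperTfr
#' @return array channels x freqs x times.
#' @export
evokedTfr <- function(epochs, freqs, times, channels = NULL, plan = NULL) {
  if (nTrials(epochs) < 2L) stop("evoked map requires at least 2 trials")
  if (is.null(channels)) channels <- ebgChannels(epochs)
  if (is.character(channels)) channels <- match(channels, epochs@channels)
  erp <- colMeans(epochs@data[, channels, , drop = FALSE])
  P <- mtPower(erp, epochs@fs, epochs@times, freqs, times, plan)
  array(P, c(length(channels), length(freqs), length(times)))
}

## baseline per leading dims: mean power over baseline time bins
baselineOf <- function(P, times, baselineWindow) {
  idx <- timeWindowIdx(times, baselineWindow)
  if (!length(idx)) stop("baseline window contains no time bins")
  nd <- length(dim(P))
  bl <- apply(P, seq_len(nd - 1L), function(v) mean(v[idx], na.rm = TRUE))
  if (any(!is.finite(bl)) || any(bl <= 0)) {
    stop("degenerate (non-positive or all-NaN) baseline power")
  }
  bl
}

#' Induced (non-phase-locked) power in decibels
#'
#' Removes the phase-locked response and expresses the remainder in dB
#' relative to the pre-stimulus baseline.  Two conventions are available:
#' \describe{
#'   \item{\code{"power"} (default)}{induced power is supplied directly
#'     (mean per-trial power of epochs with the trial-average waveform
#'     subtracted; see \code{\link{subjectContrastMap}}) or, if absent,
#'     formed as max(total - evoked, 0); it is then baseline-normalized and
#'     converted to dB.  A fully phase-locked response cancels to ~0 dB and
#'     a fully random-phase response is preserved.}
#'   \item{\code{"db"}}{total and evoked maps are each baseline-normalized
#'     and dB-converted, then subtracted (total dB - evoked dB).}
#' }
#'
#' @param total mean per-trial power array (channels x freqs x times, or
#'   freqs x times).
#' @param evoked evoked power array of the same shape.
#' @param times time axis of the maps.
#' @param baselineWindow c(t0, t1) baseline window, s.
#' @param method \code{"power"} or \code{"db"}.
#' @param inducedPower optional induced power of the same shape (preferred
#'   input for \code{method = "power"}).
#' @param floorRatio lower clip of the power/baseline ratio before taking
#'   logs (numerical guard; bounds the map at 10*log10(floorRatio) dB).
#' @return array of the same shape, in dB; kind "induced".
#' @export
inducedDb <- function(total, evoked, times, baselineWindow,
                      method = c("power", "db"), inducedPower = NULL,
                      floorRatio = 1e-2) {
  method <- match.arg(method)
  shp <- dim(total)
  dbOf <- function(P) {
    bl <- baselineOf(P, times, baselineWindow)
    ratio <- P / array(bl, shp)
    10 * log10(pmax(ratio, floorRatio))
  }
  if (method == "power") {
    ip <- if (!is.null(inducedPower)) inducedPower else pmax(total - evoked, 0)
    dbOf(ip)
  } else {
    dbOf(total) - dbOf(evoked)
  }
}

#' Odor-versus-sniff contrast, averaged over EBG electrodes
#'
#' Element-wise difference of the induced dB maps (odor minus sniff),
#' averaged over channels: the subject-level contrast map.
#'
#' @param inducedOdor,inducedSniff channels x freqs x times dB arrays on the
#'   same grid.
#' @param freqs,times map axes.
#' @return a \code{\linkS4class{TimeFreqMap}} of kind \code{"contrast"}.
#' @export
odorVsSniff <- function(inducedOdor, inducedSniff, freqs, times) {
  if (!identical(dim(inducedOdor), dim(inducedSniff))) {
    stop("odor and sniff maps must share one grid")
  }
  diffMap <- inducedOdor - inducedSniff
  vals <- colMeans(diffMap)
  timeFreqMap(vals, freqs, times,
    kind = "contrast", units = "dB",
    info = list(channels = dim(inducedOdor)[1L])
  )
}

#' Subject-level odor-vs-sniff contrast map
#'
#' Full per-subject time-frequency path: for each condition, subtract the
#' trial-average (evoked) waveform, compute per-trial multitaper power of
#' the residual (induced power), average over trials, baseline-normalize to
#' dB per channel and frequency, then contrast odor against sniff and
#' average over the four EBG electrodes.  Artifact-flagged trials are
#' excluded.
#'
#' @param epochs one subject's \code{\linkS4class{EpochSet}} containing both
#'   conditions.
#' @param freqs,times analysis axes.
#' @param baselineWindow pre-stimulus baseline, s (default c(-1.5, -0.5);
#'   choose a window inside the valid, non-NaN part of the map).
#' @param returnTrials also compute per-trial odor contrast maps (trial
#'   induced dB minus the subject's sniff induced dB)?
#' @param plan optional taper plan.
#' @return list with \code{map} (contrast \code{\linkS4class{TimeFreqMap}}),
#'   \code{trialMaps} (trials x freqs x times array or NULL),
#'   \code{inducedOdor}/\code{inducedSniff} (channels x freqs x times dB
#'   arrays) and \code{nTrials} (named count of clean trials used).
#' @export
subjectContrastMap <- function(epochs, freqs, times,
                               baselineWindow = c(-1.5, -0.5),
                               returnTrials = FALSE, plan = NULL) {
  if (is.null(plan)) {
    plan <- planTapers(freqs, epochs@fs, diff(range(epochs@times)) + 1 / epochs@fs)
  }
  ebg <- ebgChannels(epochs)
  nch <- length(ebg)
  res <- list()
  nUsed <- c(odor = 0L, sniff = 0L)
  trialDb <- NULL
  for (cond in c("odor", "sniff")) {
    sub <- cleanTrials(epochs, cond)
    nt <- nTrials(sub)
    if (nt < 2L) stop(sprintf("need at least 2 clean '%s' trials", cond))
    nUsed[cond] <- nt
    dat <- sub@data[, ebg, , drop = FALSE]
    erp <- colMeans(dat)
    for (tr in seq_len(nt)) dat[tr, , ] <- dat[tr, , ] - erp
    M <- matrix(dat, nrow = nt * nch)
    P <- mtPower(M, epochs@fs, epochs@times, freqs, times, plan)
    P <- array(P, c(nt, nch, length(freqs), length(times)))
    Pm <- colMeans(P)
    bl <- baselineOf(Pm, times, baselineWindow)
    db <- 10 * log10(pmax(Pm / array(bl, dim(Pm)), 1e-2))
    res[[cond]] <- db
    if (cond == "odor" && returnTrials) {
      trialDb <- array(NA_real_, c(nt, nch, length(freqs), length(times)))
      for (tr in seq_len(nt)) {
        trialDb[tr, , , ] <- 10 * log10(pmax(P[tr, , , ] / array(bl, dim(Pm)), 1e-2))
      }
    }
  }
  map <- odorVsSniff(res$odor, res$sniff, freqs, times)
  map@info <- c(map@info, list(
    subject = epochs@subject, group = epochs@group,
    baselineWindow = baselineWindow, nTrials = nUsed
  ))
  trialMaps <- NULL
  if (returnTrials) {
    nt <- dim(trialDb)[1L]
    trialMaps <- array(NA_real_, c(nt, length(freqs), length(times)))
    for (tr in seq_len(nt)) {
      dTr <- array(trialDb[tr, , , ], dim(res$sniff))
      trialMaps[tr, , ] <- colMeans(dTr - res$sniff)
    }
  }
  list(
    map = map, trialMaps = trialMaps, inducedOdor = res$odor,
    inducedSniff = res$sniff, nTrials = nUsed
  )
}
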