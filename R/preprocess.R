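## Preprocessing: epoching, re-referencing, notch, trigger-delay correction,
## Hilbert-envelope artifact screening, EOG regression ocular correction.

#' Zero-phase Butterworth band-pass
#'
#' Order-2 (per direction) Butterworth band-pass applied forward-backward
#' with \code{signal::filtfilt}, i.e. zero phase shift.
#'
#' @param x numeric vector.
#' @param band c(low, high) in Hz.
#' @param fs sampling rate, Hz.
#' @param order filter order per direction.
#' @return filtered vector.
#' @export
bandpassFilter <- function(x, band, fs, order = 2) {
  wn <- band / (fs / 2)
  if (any(wn <= 0) || any(wn >= 1)) stop("band edges must lie in (0, fs/2)")
  bf <- signal::butter(order, wn, type = "pass")
  signal::filtfilt(bf, x)
}

#' Epoch a continuous recording
#'
#' Cuts one epoch per event marker.  Epochs use the package's half-open
#' sample convention: N = round(fs * (t1 - t0)) samples at times
#' t0 + k/fs, k = 0..N-1, with t = 0 at the event sample.  Events whose
#' window would leave the record are rejected with a warning, not an error.
#'
#' @param recording list with elements \code{data} (channels x samples
#'   matrix, microvolts), \code{fs} (Hz), \code{channels} (labels) and
#'   \code{events} (data.frame with columns \code{sample} -- 1-based sample
#'   index of stimulus onset -- and \code{condition}).
#' @param window c(t0, t1) in seconds relative to the event, default
#'   c(-2, 2).
#' @param subject,group metadata for the resulting EpochSet.
#' @return an \code{\linkS4class{EpochSet}}; trial order preserves event
#'   order.
#' @export
epochRecording <- function(recording, window = c(-2, 2),
                           subject = "s1", group = "Control") {
  stopifnot(is.matrix(recording$data), recording$fs > 0)
  fs <- recording$fs
  n <- as.integer(roundHalfUp(fs * diff(window)))
  off0 <- as.integer(roundHalfUp(window[1L] * fs))
  nSamp <- ncol(recording$data)
  ev <- recording$events
  ok <- ev$sample + off0 >= 1L & ev$sample + off0 + n - 1L <= nSamp
  if (any(!ok)) {
    warning(sprintf(
      "%d event(s) too close to the record edge were rejected", sum(!ok)
    ))
  }
  ev <- ev[ok, , drop = FALSE]
  dat <- array(0, c(nrow(ev), nrow(recording$data), n))
  for (i in seq_len(nrow(ev))) {
    idx <- ev$sample[i] + off0 + 0:(n - 1L)
    dat[i, , ] <- recording$data[, idx]
  }
  epochSet(dat, fs,
    times = window[1L] + (seq_len(n) - 1L) / fs,
    channels = recording$channels,
    condition = as.character(ev$condition),
    subject = subject, group = group
  )
}

#' Re-reference to the mastoid average
#'
#' Subtracts 0.5 (M1 + M2) sample-wise from every non-mastoid channel.
#'
#' @param epochs an \code{\linkS4class{EpochSet}} containing channels
#'   \code{"M1"} and \code{"M2"}.
#' @param mastoids labels of the two mastoid channels.
#' @return re-referenced \code{EpochSet}.
#' @export
rereference <- function(epochs, mastoids = c("M1", "M2")) {
  mi <- match(mastoids, epochs@channels)
  if (anyNA(mi)) {
    stop(sprintf(
      "mastoid channel(s) missing: %s",
      paste(mastoids[is.na(mi)], collapse = ", ")
    ))
  }
  ref <- (epochs@data[, mi[1L], , drop = FALSE] +
    epochs@data[, mi[2L], , drop = FALSE]) / 2
  out <- epochs
  for (ch in seq_along(epochs@channels)) {
    if (ch %in% mi) next
    out@data[, ch, ] <- epochs@data[, ch, ] - ref[, 1L, ]
  }
  out
}

#' 50 Hz power-line notch
#'
#' Second-order IIR notch (quality factor 30 by default) applied
#' forward-backward for zero phase to every trial and channel.  The
#' effective (two-pass) response attenuates the line frequency by well over
#' 30 dB while leaving 40 and 60 Hz within 1 dB.
#'
#' @param epochs an \code{\linkS4class{EpochSet}}.
#' @param freq notch frequency, Hz.
#' @param q quality factor (freq / -3 dB bandwidth, single pass).
#' @return filtered \code{EpochSet}.
#' @export
notchLine <- function(epochs, freq = 50, q = 30) {
  fs <- epochs@fs
  if (fs <= 2 * freq) stop("sampling rate too low for the notch frequency")
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  out <- epochs
  d <- dim(epochs@data)
  for (tr in seq_len(d[1L])) {
    for (ch in seq_len(d[2L])) {
      out@data[tr, ch, ] <- signal::filtfilt(b, a, epochs@data[tr, ch, ])
    }
  }
  out
}

#' Correct the olfactometer trigger delay
#'
#' Shifts the epoch so that t = 0 marks odor arrival at the nasal cavity
#' rather than the electrical trigger: the data are advanced by
#' round-half-up(delay * fs) samples and the window re-cropped at the end
#' (the time axis keeps its origin).  Applied identically to odor and sniff
#' trials.
#'
#' @param epochs an \code{\linkS4class{EpochSet}}.
#' @param delay trigger-to-nose delay in seconds (default 0.150).
#' @return delay-corrected \code{EpochSet} (shorter by the shift).
#' @export
correctTriggerDelay <- function(epochs, delay = 0.150) {
  if (delay < 0) stop("delay must be >= 0")
  if (delay > -epochs@times[1L]) {
    stop("delay exceeds the pre-stimulus window")
  }
  shift <- as.integer(roundHalfUp(delay * epochs@fs))
  if (shift == 0L) return(epochs)
  n <- length(epochs@times)
  out <- epochs
  out@data <- epochs@data[, , (shift + 1L):n, drop = FALSE]
  out@times <- epochs@times[seq_len(n - shift)]
  out
}

#' Detect blink and muscle artifact trials
#'
#' Implements the envelope-threshold screen: band-pass filter (blink band on
#' the EOG channels, muscle band on the EBG channels), take the Hilbert
#' (analytic-signal) envelope, z-score the envelope against the distribution
#' pooled over all trials per channel and band, and flag a trial whose
#' envelope exceeds the cutoff z anywhere.  Zero-variance envelopes give
#' z = 0.  Blink takes precedence over muscle when both exceed threshold.
#'
#' @param epochs an \code{\linkS4class{EpochSet}} with EOG channels.
#' @param muscleZ,blinkZ cutoff z values (defaults 8 and 4).
#' @param blinkBand,muscleBand filter bands in Hz.
#' @return the \code{EpochSet} with updated \code{artifactFlags}; the
#'   retention fraction is attached as attribute \code{"retention"}.
#' @export
detectArtifacts <- function(epochs, muscleZ = 8, blinkZ = 4,
                            blinkBand = c(0.5, 4), muscleBand = c(20, 45)) {
  fs <- epochs@fs
  eog <- grep("^EOG", epochs@channels)
  ebg <- ebgChannels(epochs@channels)
  if (!length(eog)) stop("EOG channels required for blink detection")
  muscleBand[2L] <- min(muscleBand[2L], 0.45 * fs)
  d <- dim(epochs@data)
  nTr <- d[1L]

  maxZ <- function(chans, band) {
    ## trials x channels matrix of per-trial max envelope z
    out <- matrix(0, nTr, length(chans))
    for (j in seq_along(chans)) {
      env <- matrix(0, nTr, d[3L])
      for (tr in seq_len(nTr)) {
        filt <- bandpassFilter(epochs@data[tr, chans[j], ], band, fs)
        env[tr, ] <- Mod(analyticSignal(filt))
      }
      mu <- mean(env)
      sg <- sd(env)
      z <- if (sg > 0) (env - mu) / sg else env * 0
      out[, j] <- apply(z, 1L, max)
    }
    out
  }

  blinkHit <- apply(maxZ(eog, blinkBand), 1L, max) > blinkZ
  muscleHit <- apply(maxZ(ebg, muscleBand), 1L, max) > muscleZ

  flags <- rep("clean", nTr)
  flags[muscleHit] <- "muscle"
  flags[blinkHit] <- "blink" # blink takes precedence
  if (all(flags != "clean")) {
    stop("all trials flagged as artifacts; review thresholds")
  }
  out <- epochs
  out@artifactFlags <- flags
  attr(out, "retention") <- mean(flags == "clean")
  out
}

#' Ocular correction by EOG regression
#'
#' Removes eye-movement influence from the EBG channels by ordinary
#' least-squares regression of each EBG channel on the two vertical EOG
#' channels (propagation coefficients estimated on the pooled clean-trial
#' epoch data, subtraction applied sample-wise) -- the regression core of
#' aligned-artifact EOG correction.  Output variance on EBG channels never
#' exceeds input variance.
#'
#' @param epochs an \code{\linkS4class{EpochSet}} with EOG channels.
#' @return corrected \code{EpochSet}.
#' @export
correctOcular <- function(epochs) {
  eog <- grep("^EOG", epochs@channels)
  ebg <- ebgChannels(epochs@channels)
  if (!length(eog)) stop("EOG channels required for ocular correction")
  keep <- which(epochs@artifactFlags == "clean")
  if (!length(keep)) keep <- seq_len(nTrials(epochs))
  n <- length(epochs@times)
  X <- do.call(rbind, lapply(keep, function(tr) {
    t(matrix(epochs@data[tr, eog, ], nrow = length(eog)))
  }))
  xtx <- crossprod(X)
  if (rcond(xtx) < 1e-12) {
    warning("singular EOG covariance; ocular correction skipped")
    return(epochs)
  }
  out <- epochs
  for (ch in ebg) {
    y <- as.numeric(t(epochs@data[keep, ch, ]))
    beta <- solve(xtx, crossprod(X, y))
    for (tr in seq_len(nTrials(epochs))) {
      pred <- drop(t(matrix(epochs@data[tr, eog, ], nrow = length(eog))) %*% beta)
      out@data[tr, ch, ] <- epochs@data[tr, ch, ] - pred
    }
  }
  out
}

#' Run the standard preprocessing chain on one subject
#'
#' rereference -> notch (optional) -> trigger-delay correction (optional)
#' -> artifact screen -> ocular correction.
#'
#' @param epochs an \code{\linkS4class{EpochSet}}.
#' @param notch apply the 50 Hz notch?
#' @param delay trigger delay in seconds (0 skips the shift).
#' @param muscleZ,blinkZ artifact cutoffs.
#' @return preprocessed \code{EpochSet} with artifact flags set; retention
#'   fraction in attribute \code{"retention"}.
#' @export
preprocessSubject <- function(epochs, notch = TRUE, delay = 0,
                              muscleZ = 8, blinkZ = 4) {
  out <- rereference(epochs)
  if (notch) out <- notchLine(out)
  if (delay > 0) out <- correctTriggerDelay(out, delay)
  out <- detectArtifacts(out, muscleZ = muscleZ, blinkZ = blinkZ)
  ret <- attr(out, "retention")
  out <- correctOcular(out)
  attr(out, "retention") <- ret
  out
}
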