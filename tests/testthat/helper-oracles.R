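## Independent reference implementations used to validate the package's
## numerics.  These deliberately use different algorithms from the package
## code: DPSS tapers come from the dense sinc concentration matrix (the
## defining eigenproblem) rather than the tridiagonal commuting operator,
## and the spectrogram oracle is a naive per-bin windowed-DFT loop.

## DPSS by the defining concentration problem: eigenvectors of
## S[i,j] = sin(2*pi*w*(i-j)) / (pi*(i-j)), S[i,i] = 2*w, w = NW/n.
oracleDpss <- function(n, nw, k) {
  w <- nw / n
  d <- outer(seq_len(n), seq_len(n), "-")
  S <- sin(2 * pi * w * d) / (pi * d)
  diag(S) <- 2 * w
  e <- eigen(S, symmetric = TRUE)
  v <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
    lead <- which(abs(v[, j]) > 1e-7 * max(abs(v[, j])))[1L]
    if (v[lead, j] < 0) v[, j] <- -v[, j]
  }
  v
}

## Naive windowed-DFT multitaper power at one (freq, time) bin: extract the
## window around the snapped centre sample, multiply by each oracle taper,
## correlate against a complex exponential at f, average |.|^2 over tapers.
## Returns NA when the window leaves the epoch.
oracleMtBin <- function(x, fs, times, f, t0, L, nw, k) {
  n <- length(x)
  centre <- floor((t0 - times[1L]) * fs + 0.5) + 1L
  h <- (L - 1L) %/% 2L
  if (centre - h < 1L || centre + h > n) return(NA_real_)
  seg <- x[(centre - h):(centre + h)]
  tap <- oracleDpss(L, nw, k)
  rel <- ((0:(L - 1L)) - h) / fs
  ex <- exp(-2i * pi * f * rel)
  mean(vapply(seq_len(k), function(j) Mod(sum(seg * tap[, j] * ex))^2, numeric(1L)))
}

## ICC(2,k) by brute-force two-way ANOVA via stats::aov on the long format.
oracleIcc2k <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  long <- data.frame(
    y = as.vector(mat),
    row = factor(rep(seq_len(n), times = k)),
    col = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(aov(y ~ row + col, data = long))[[1L]][["Mean Sq"]]
  msr <- ms[1L]
  msc <- ms[2L]
  mse <- ms[3L]
  (msr - mse) / (msr + (msc - mse) / n)
}

## Deterministic artifact-screening fixture: per-trial sinusoids whose
## Hilbert envelopes are nearly constant (so no clean trial can reach the
## z cutoffs), with optional large blink / muscle events on chosen trials.
makeArtifactFixture <- function(fs = 256, nTrials = 20, blinkTrials = integer(),
                                muscleTrials = integer(), scale = 10) {
  times <- seq(-1, 1 - 1 / fs, by = 1 / fs)
  n <- length(times)
  channels <- c("EBG1", "EBG2", "M1", "M2", "EOGL", "EOGR")
  dat <- array(0, c(nTrials, length(channels), n))
  for (tr in seq_len(nTrials)) {
    for (ch in seq_along(channels)) {
      ## near-silent mastoids keep re-referencing close to the identity
      gain <- if (channels[ch] %in% c("M1", "M2")) 0.01 else 1 + 0.01 * ch
      ## in-band tones on every channel keep the blink (0.5-4 Hz) and
      ## muscle (20-45 Hz) envelopes nearly constant, so clean trials can
      ## never reach the z cutoffs; per-channel phases avoid collinearity
      dat[tr, ch, ] <- (1 + 0.02 * tr) * gain * (
        0.8 * sin(2 * pi * 2 * times + 0.2 * ch) +
          sin(2 * pi * 10 * times + 0.15 * ch * tr) +
          0.5 * sin(2 * pi * 30 * times + tr + 0.1 * ch)
      )
    }
  }
  blinkShape <- -(times / 0.15) * exp(0.5 - times^2 / (2 * 0.15^2))
  for (tr in blinkTrials) {
    dat[tr, 5L, ] <- dat[tr, 5L, ] + scale * 15 * blinkShape
    dat[tr, 6L, ] <- dat[tr, 6L, ] + scale * 15 * blinkShape
  }
  muscleShape <- exp(-times^2 / (2 * 0.08^2)) * sin(2 * pi * 35 * times)
  for (tr in muscleTrials) {
    dat[tr, 1L, ] <- dat[tr, 1L, ] + scale * 15 * muscleShape
    dat[tr, 2L, ] <- dat[tr, 2L, ] + scale * 15 * muscleShape
  }
  epochSet(dat, fs,
    times = times, channels = channels,
    condition = rep("odor", nTrials)
  )
}
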