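## Small numeric primitives shared across modules.

#' Analytic signal via the frequency domain
#'
#' Returns the complex analytic signal whose real part is \code{x} and whose
#' modulus is the instantaneous (Hilbert) envelope.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @export
analyticSignal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Seeded 1/f^chi background noise
#'
#' Spectrally shaped Gaussian noise with power spectral density proportional
#' to 1/f^chi, scaled to unit standard deviation (the caller multiplies by the
#' desired RMS).  The standard surrogate for electrophysiological background
#' activity.
#'
#' @param n number of samples.
#' @param fs sampling rate, Hz.
#' @param exponent spectral exponent chi (1 = pink noise).
#' @return numeric vector with sd approximately 1.
#' @export
oneOverFNoise <- function(n, fs, exponent = 1) {
  nf <- n %/% 2L
  f <- (1:nf) * fs / n
  amp <- f^(-exponent / 2)
  re <- rnorm(nf) * amp
  im <- rnorm(nf) * amp
  spec <- complex(real = re, imaginary = im)
  full <- complex(length.out = n)
  full[2:(nf + 1L)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1L] <- complex(real = re[nf], imaginary = 0)
    full[(nf + 2L):n] <- Conj(spec[(nf - 1L):1L])
  } else {
    full[(nf + 2L):n] <- Conj(spec[nf:1L])
  }
  x <- Re(fft(full, inverse = TRUE)) / n
  s <- sd(x)
  if (s == 0) x else x / s
}

#' Decibel ratio
#' @param p,ref power and reference power.
#' @return 10 log10(p / ref).
#' @keywords internal
dbRatio <- function(p, ref) 10 * log10(p / ref)

## round-half-up to integer (base round() is banker's rounding)
roundHalfUp <- function(x) floor(x + 0.5)

## indices of time-axis bins inside [w[1], w[2]] (inclusive, tolerance for fp)
timeWindowIdx <- function(times, w) {
  which(times >= w[1L] - 1e-9 & times <= w[2L] + 1e-9)
}

## stop unless x is a scalar finite number
assertScalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite scalar", name), call. = FALSE)
  }
  invisible(x)
}
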