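makeRecording <- function(fs = 256, dur = 30, nEvents = 5) {
  set.seed(21)
  nSamp <- fs * dur
  channels <- c("EBG1", "EBG2", "M1", "M2", "EOGL", "EOGR")
  data <- matrix(rnorm(length(channels) * nSamp), length(channels), nSamp)
  events <- data.frame(
    sample = seq(3 * fs, by = 5 * fs, length.out = nEvents),
    condition = rep(c("odor", "sniff"), length.out = nEvents)
  )
  list(data = data, fs = fs, channels = channels, events = events)
}

test_that("epochRecording implements the half-open sample convention", {
  rec <- makeRecording()
  ep <- epochRecording(rec, window = c(-2, 2))
  expect_equal(nTrials(ep), 5)
  expect_equal(dim(ep@data)[3], 256 * 4) # round(fs * duration) samples
  expect_equal(ep@times[1], -2)
  expect_equal(ep@times[length(ep@times)], 2 - 1 / 256)
  ## t = 0 lands exactly on the event sample
  i0 <- which(abs(ep@times) < 1e-12)
  expect_equal(ep@data[1, 1, i0], rec$data[1, rec$events$sample[1]])
})

test_that("epochRecording rejects edge events with a warning", {
  rec <- makeRecording()
  rec$events$sample[1] <- 10 # window would start before the record
  expect_warning(ep <- epochRecording(rec, window = c(-2, 2)), "rejected")
  expect_equal(nTrials(ep), 4)
})

test_that("rereference subtracts the mastoid average and leaves mastoids alone", {
  rec <- makeRecording()
  ep <- epochRecording(rec, window = c(-1, 1))
  rr <- rereference(ep)
  refSig <- (ep@data[2, 3, ] + ep@data[2, 4, ]) / 2
  expect_equal(rr@data[2, 1, ], ep@data[2, 1, ] - refSig)
  expect_equal(rr@data[2, 3, ], ep@data[2, 3, ]) # mastoids untouched
  ep2 <- ep
  ep2@channels[3] <- "A1"
  expect_error(rereference(ep2), "mastoid")
})

test_that("notchLine meets the attenuation contract at 50 Hz and neighbours", {
  fs <- 512
  times <- seq(-2, 2 - 1 / fs, by = 1 / fs)
  mkTone <- function(f) {
    dat <- array(0, c(1, 1, length(times)))
    dat[1, 1, ] <- sin(2 * pi * f * times)
    epochSet(dat, fs, times = times, channels = "EBG1")
  }
  midAmp <- function(ep) {
    mid <- ebgtools:::timeWindowIdx(ep@times, c(-1, 1))
    sqrt(mean(ep@data[1, 1, mid]^2)) * sqrt(2)
  }
  att <- vapply(c(40, 50, 60), function(f) {
    -20 * log10(midAmp(notchLine(mkTone(f))) / midAmp(mkTone(f)))
  }, numeric(1))
  expect_gt(att[2], 30) # >= 30 dB at the line frequency
  expect_lt(abs(att[1]), 1) # <= 1 dB at 40 Hz
  expect_lt(abs(att[3]), 1) # <= 1 dB at 60 Hz
  expect_error(notchLine(mkTone(10), freq = 50, q = 30) -> x, NA)
  expect_error(notchLine(epochSet(array(0, c(1, 1, 80)), 80), freq = 50), "too low")
})

test_that("correctTriggerDelay shifts by round-half-up samples and recrops", {
  fs <- 512
  times <- seq(-2, 2 - 1 / fs, by = 1 / fs)
  dat <- array(0, c(1, 1, length(times)))
  dat[1, 1, ] <- seq_along(times)
  ep <- epochSet(dat, fs, times = times, channels = "EBG1")
  out <- correctTriggerDelay(ep, delay = 0.150)
  shift <- floor(0.150 * 512 + 0.5) # 77 samples
  expect_equal(length(out@times), length(times) - shift)
  expect_equal(out@data[1, 1, 1], shift + 1)
  expect_equal(out@times[1], -2) # time origin preserved
  expect_identical(correctTriggerDelay(ep, 0), ep)
  expect_error(correctTriggerDelay(ep, 2.5), "pre-stimulus")
})

test_that("detectArtifacts flags exactly the injected trials with blink precedence", {
  ep <- makeArtifactFixture(blinkTrials = c(3, 7), muscleTrials = c(7, 12))
  out <- detectArtifacts(ep)
  flags <- artifactFlags(out)
  expect_equal(which(flags == "blink"), c(3L, 7L)) # blink wins on trial 7
  expect_equal(which(flags == "muscle"), 12L)
  expect_equal(attr(out, "retention"), 17 / 20)
})

test_that("detectArtifacts never flags the clean constructed fixture", {
  ep <- makeArtifactFixture()
  out <- detectArtifacts(ep)
  expect_true(all(artifactFlags(out) == "clean"))
})

test_that("detectArtifacts degenerate paths", {
  ## zero-variance signal: envelopes constant -> z = 0 -> clean
  dat <- array(0, c(4, 6, 256))
  ep <- epochSet(dat, 256, channels = c("EBG1", "EBG2", "M1", "M2", "EOGL", "EOGR"))
  expect_true(all(artifactFlags(detectArtifacts(ep)) == "clean"))
  ## cutoff so low every trial trips it -> error
  ep2 <- makeArtifactFixture(nTrials = 4)
  expect_error(detectArtifacts(ep2, blinkZ = 0.01), "all trials")
  ## missing EOG -> error
  ep3 <- epochSet(array(0, c(2, 2, 100)), 100, channels = c("EBG1", "EBG2"))
  expect_error(detectArtifacts(ep3), "EOG")
})

test_that("correctOcular removes EOG-propagated signal without inflating variance", {
  fs <- 128
  times <- seq(-1, 1 - 1 / fs, by = 1 / fs)
  set.seed(23)
  nTr <- 10
  channels <- c("EBG1", "EBG2", "M1", "M2", "EOGL", "EOGR")
  dat <- array(rnorm(nTr * 6 * length(times), 0, 0.5), c(nTr, 6, length(times)))
  ## a known ocular source leaks into EBG1 with gain 0.4
  for (tr in seq_len(nTr)) {
    ocular <- 5 * sin(2 * pi * 1.3 * times + tr)
    dat[tr, 5, ] <- dat[tr, 5, ] + ocular
    dat[tr, 6, ] <- dat[tr, 6, ] + ocular
    dat[tr, 1, ] <- dat[tr, 1, ] + 0.4 * ocular
  }
  ep <- epochSet(dat, fs, times = times, channels = channels)
  out <- correctOcular(ep)
  corBefore <- abs(cor(ep@data[1, 1, ], ep@data[1, 5, ]))
  corAfter <- abs(cor(out@data[1, 1, ], out@data[1, 5, ]))
  expect_lt(corAfter, 0.1)
  expect_gt(corBefore, 0.5)
  expect_lt(var(as.vector(out@data[, 1, ])), var(as.vector(ep@data[, 1, ])))
  ## singular EOG covariance -> warning, unchanged data
  ep2 <- ep
  ep2@data[, 5, ] <- 0
  ep2@data[, 6, ] <- 0
  expect_warning(out2 <- correctOcular(ep2), "singular")
  expect_identical(out2@data, ep2@data)
})

test_that("preprocessSubject chains the stages and reports retention", {
  ep <- makeArtifactFixture(blinkTrials = 2)
  out <- preprocessSubject(ep, notch = TRUE, delay = 0.1)
  expect_equal(attr(out, "retention"), 19 / 20)
  expect_lt(length(out@times), length(ep@times))
})
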