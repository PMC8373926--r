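makeToneEpochs <- function(fs = 128, nTrials = 4, f0 = 10, amp = 2,
                           t0 = 0.3, sd = 0.1, seed = 5) {
  set.seed(seed)
  times <- seq(-1, 1 - 1 / fs, by = 1 / fs)
  channels <- c("EBG1", "EBG2")
  dat <- array(rnorm(nTrials * 2 * length(times), 0, 0.1),
    c(nTrials, 2, length(times))
  )
  burst <- amp * exp(-(times - t0)^2 / (2 * sd^2)) * cos(2 * pi * f0 * times)
  for (tr in seq_len(nTrials)) {
    for (ch in 1:2) dat[tr, ch, ] <- dat[tr, ch, ] + burst
  }
  epochSet(dat, fs,
    times = times, channels = channels,
    condition = rep("odor", nTrials)
  )
}

test_that("planTapers implements the frequency-adaptive rules", {
  plan <- planTapers(c(2, 10, 40), fs = 256, epochDuration = 4)
  expect_equal(plan$T, 2 / c(2, 10, 40))
  expect_equal(plan$W, 0.8 * c(2, 10, 40))
  expect_equal(plan$K, rep(2L, 3))
  expect_true(all(plan$L %% 2 == 1))
  ## epoch shorter than two cycles: window capped, taper count drops
  capped <- planTapers(0.5, fs = 256, epochDuration = 1)
  expect_equal(capped$T, 1)
  expect_equal(capped$K, 1L) # floor(2*1*0.4 - 1) = 0 -> floored at 1
  expect_error(planTapers(200, fs = 256, epochDuration = 4), "fs/2")
})

test_that("multitaperTfr localizes a Gabor burst at its frequency and time", {
  ep <- makeToneEpochs()
  freqs <- seq(4, 40, by = 2)
  times <- seq(-0.6, 0.6, by = 0.05)
  P <- multitaperTfr(ep, freqs, times)
  expect_equal(dim(P), c(4L, 2L, length(freqs), length(times)))
  avg <- colMeans(P)[1, , ] # channel 1, freq x time
  ## along the 10 Hz row the burst peaks at its centre time
  row10 <- avg[which(freqs == 10), ]
  expect_equal(times[which.max(row10)], 0.3, tolerance = 0.06)
  ## the burst is localized: far-off bins carry a fraction of its power
  at <- function(f, t) avg[which.min(abs(freqs - f)), which.min(abs(times - t))]
  expect_gt(max(row10), 20 * at(10, -0.4))
  ## the 30 Hz bin's band (W = 24 Hz) reaches the 10 Hz burst by design,
  ## but captures less of it than the on-frequency bin and stays
  ## time-localized
  expect_gt(at(10, 0.3), at(30, 0.3))
  expect_gt(at(30, 0.3), 5 * at(30, -0.4))
})

test_that("bins whose window leaves the epoch are NaN, interior bins are finite", {
  ep <- makeToneEpochs()
  ## at 4 Hz the window is 0.5 s: centres within 0.25 s of either edge are NaN
  P <- multitaperTfr(ep, 4, c(-0.9, 0, 0.9))
  expect_true(all(is.na(P[, , 1, c(1, 3)])))
  expect_true(all(is.finite(P[, , 1, 2])))
})

test_that("evokedTfr keeps phase-locked and loses phase-random energy", {
  fs <- 128
  times <- seq(-1, 1 - 1 / fs, by = 1 / fs)
  nTr <- 60
  burst <- exp(-times^2 / (2 * 0.1^2))
  locked <- array(0, c(nTr, 1, length(times)))
  random <- array(0, c(nTr, 1, length(times)))
  set.seed(6)
  for (tr in seq_len(nTr)) {
    locked[tr, 1, ] <- burst * cos(2 * pi * 10 * times)
    random[tr, 1, ] <- burst * cos(2 * pi * 10 * times + runif(1, 0, 2 * pi))
  }
  mk <- function(d) {
    epochSet(d, fs,
      times = times, channels = "EBG1",
      condition = rep("odor", dim(d)[1])
    )
  }
  evL <- evokedTfr(mk(locked), 10, 0)
  evR <- evokedTfr(mk(random), 10, 0)
  totL <- mean(multitaperTfr(mk(locked), 10, 0, channels = 1)[, 1, 1, 1])
  expect_gt(evL[1, 1, 1], 0.5 * totL) # phase-locked survives averaging
  expect_lt(evR[1, 1, 1], 0.1 * totL) # random phase cancels
  expect_error(evokedTfr(mk(locked[1, , , drop = FALSE]), 10, 0), "at least 2")
})

test_that("inducedDb conventions behave at the extremes", {
  times <- seq(-1, 1, by = 0.05)
  shape <- c(2, length(times))
  total <- array(1, shape)
  evoked <- array(0.5, shape)
  ## method "power" with explicit induced power equal to baseline -> 0 dB
  out <- inducedDb(total, evoked, times, c(-1, -0.5),
    method = "power", inducedPower = total
  )
  expect_equal(out, array(0, shape), ignore_attr = TRUE)
  ## method "db": equal relative changes cancel
  out2 <- inducedDb(total * 2, evoked * 2, times, c(-1, -0.5), method = "db")
  expect_equal(out2, array(0, shape), ignore_attr = TRUE)
  ## floor bounds the map
  tiny <- total
  tiny[, times > 0] <- 1e-9
  out3 <- inducedDb(tiny, evoked, times, c(-1, -0.5),
    method = "power", inducedPower = tiny, floorRatio = 1e-2
  )
  expect_equal(min(out3), -20)
  expect_error(
    inducedDb(total, evoked, times, c(5, 6), method = "db"),
    "baseline"
  )
})

test_that("odorVsSniff subtracts and averages over channels", {
  freqs <- 1:3
  times <- seq(0, 1, by = 0.5)
  a <- array(2, c(4, 3, 3))
  b <- array(0.5, c(4, 3, 3))
  m <- odorVsSniff(a, b, freqs, times)
  expect_s4_class(m, "TimeFreqMap")
  expect_equal(tfValues(m), matrix(1.5, 3, 3))
  expect_error(odorVsSniff(a, b[1:2, , ], freqs, times), "grid")
})

test_that("subjectContrastMap is deterministic and flags artifact trials out", {
  fs <- 128
  times <- seq(-1, 1 - 1 / fs, by = 1 / fs)
  set.seed(7)
  nTr <- 8
  dat <- array(rnorm(nTr * 3 * length(times)), c(nTr, 3, length(times)))
  ep <- epochSet(dat, fs,
    times = times, channels = c("EBG1", "EBG2", "EOGL"),
    condition = rep(c("odor", "sniff"), each = 4)
  )
  freqs <- seq(8, 32, by = 8)
  tgrid <- seq(-0.5, 0.5, by = 0.1)
  r1 <- subjectContrastMap(ep, freqs, tgrid,
    baselineWindow = c(-0.5, -0.2),
    returnTrials = TRUE
  )
  r2 <- subjectContrastMap(ep, freqs, tgrid, baselineWindow = c(-0.5, -0.2))
  expect_identical(tfValues(r1$map), tfValues(r2$map))
  expect_equal(dim(r1$trialMaps), c(4L, length(freqs), length(tgrid)))
  ## flagging odor trials reduces the clean count used
  ep2 <- ep
  ep2@artifactFlags[1] <- "blink"
  r3 <- subjectContrastMap(ep2, freqs, tgrid, baselineWindow = c(-0.5, -0.2))
  expect_equal(unname(r3$nTrials["odor"]), 3L)
  ## too few clean trials errors
  ep3 <- ep
  ep3@artifactFlags[5:7] <- "muscle"
  expect_error(
    subjectContrastMap(ep3, freqs, tgrid, baselineWindow = c(-0.5, -0.2)),
    "at least 2"
  )
})
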