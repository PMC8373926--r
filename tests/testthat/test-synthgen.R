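smallConfig <- function(...) {
  simulationConfig(
    nPd = 3, nControl = 3, nOdorTrials = 4, nSniffTrials = 2,
    fs = 200, epochWindow = c(-1, 1),
    burstSpecs = defaultBurstSpecs(8),
    artifactRates = c(blink = 0, muscle = 0),
    ...
  )
}

test_that("generateDataset is bit-identical for the same (config, seed)", {
  cfg <- smallConfig()
  a <- generateDataset(cfg, seed = 11)
  b <- generateDataset(cfg, seed = 11)
  expect_identical(a$epochs[[1]]@data, b$epochs[[1]]@data)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth$subjectAmps, b$truth$subjectAmps)
  c <- generateDataset(cfg, seed = 12)
  expect_false(identical(a$epochs[[1]]@data, c$epochs[[1]]@data))
})

test_that("generated datasets have the configured structure", {
  cfg <- smallConfig()
  d <- generateDataset(cfg, seed = 1)
  expect_length(d$epochs, 6)
  ep <- d$epochs[[1]]
  expect_equal(dim(ep@data), c(6L, 8L, 400L)) # round(200 * 2) samples
  expect_equal(ep@times[1], -1)
  expect_equal(table(ep@condition)[["odor"]], 4L)
  expect_equal(d$truth$groups, c(rep("PD", 3), rep("Control", 3)))
  expect_equal(nrow(d$clinical), 6)
})

test_that("bursts go to the dominant group's EBG channels on the right condition", {
  bs <- defaultBurstSpecs(40)[2, ] # control-dominant 65 Hz burst at 0.46 s
  bs$freqSd <- 0
  cfg <- simulationConfig(
    nPd = 2, nControl = 2, nOdorTrials = 6, nSniffTrials = 3,
    fs = 200, epochWindow = c(-1, 1), burstSpecs = bs,
    ampSubjectSd = 0.01, artifactRates = c(blink = 0, muscle = 0),
    lineNoiseAmp = 0, noiseSd = 0.5, noiseFloorSd = 0.1
  )
  d <- generateDataset(cfg, seed = 2)
  burstPower <- function(ep, cond) {
    idx <- which(ep@condition == cond)
    win <- ebgtools:::timeWindowIdx(ep@times, c(0.41, 0.51))
    mean(ep@data[idx, 1:4, win]^2)
  }
  pdOdor <- burstPower(d$epochs[[1]], "odor")
  ctrlOdor <- burstPower(d$epochs[[3]], "odor")
  ctrlSniff <- burstPower(d$epochs[[3]], "sniff")
  mastoid <- mean(d$epochs[[3]]@data[
    d$epochs[[3]]@condition == "odor", 5:6,
    ebgtools:::timeWindowIdx(d$epochs[[3]]@times, c(0.41, 0.51))
  ]^2)
  expect_gt(ctrlOdor, 50 * pdOdor) # control >> PD on odor trials
  expect_gt(ctrlOdor, 50 * ctrlSniff) # odor-only condition
  expect_gt(ctrlOdor, 50 * mastoid) # EBG channels only
})

test_that("injectArtifacts with zero rates is the identity, labels match injections", {
  cfg <- smallConfig()
  ep <- generateDataset(cfg, seed = 3)$epochs[[1]]
  out0 <- injectArtifacts(ep, c(blink = 0, muscle = 0), seed = 1)
  expect_identical(out0$epochs@data, ep@data)
  expect_equal(nrow(out0$labels), 0)
  out <- injectArtifacts(ep, c(blink = 2, muscle = 2), seed = 4)
  expect_gt(nrow(out$labels), 0)
  expect_true(all(out$labels$type %in% c("blink", "muscle")))
  expect_true(all(out$labels$trial %in% seq_len(nTrials(ep))))
  ## injected trials actually changed, untouched trials did not
  touched <- sort(unique(out$labels$trial))
  untouched <- setdiff(seq_len(nTrials(ep)), touched)
  for (tr in touched) {
    expect_false(identical(out$epochs@data[tr, , ], ep@data[tr, , ]))
  }
  for (tr in untouched) {
    expect_identical(out$epochs@data[tr, , ], ep@data[tr, , ])
  }
  expect_error(injectArtifacts(ep, c(blink = 1)), "muscle")
})

test_that("clinical covariates respect ranges and group structure", {
  cfg <- simulationConfig(
    nPd = 40, nControl = 40, nOdorTrials = 2, nSniffTrials = 2,
    fs = 100, epochWindow = c(-0.5, 0.5),
    burstSpecs = defaultBurstSpecs(0)[0, ],
    artifactRates = c(blink = 0, muscle = 0)
  )
  cl <- generateCovariates(cfg, seed = 5)
  pd <- cl[cl$group == "PD", ]
  ctrl <- cl[cl$group == "Control", ]
  expect_true(all(pd$hy %in% seq(1, 3, by = 0.5)))
  expect_true(all(pd$duration > 0))
  expect_true(all(pd$ledd >= 0))
  expect_true(all(is.na(ctrl$ledd)))
  expect_true(all(cl$odor_id >= 0 & cl$odor_id <= 16))
  ## patients smell markedly worse on average
  expect_lt(mean(pd$odor_id), mean(ctrl$odor_id) - 3)
})

test_that("covariate coupling induces the requested correlation, zero coupling none", {
  cfg <- simulationConfig(
    nPd = 150, nControl = 2, nOdorTrials = 2, nSniffTrials = 2,
    fs = 200, epochWindow = c(-1, 1.2),
    burstSpecs = defaultBurstSpecs(8),
    artifactRates = c(blink = 0, muscle = 0),
    covariateCoupling = list(list(outcome = "ledd", burst = 1, rho = 0.7))
  )
  set.seed(6)
  amps <- matrix(rnorm(152 * 6, 8, 2), 152, 6)
  rownames(amps) <- c(sprintf("PD%02d", 1:150), sprintf("C%02d", 1:2))
  cl <- generateCovariates(cfg, subjectAmps = amps, seed = 6)
  pdIdx <- which(cl$group == "PD")
  r <- cor(cl$ledd[pdIdx], amps[pdIdx, 1])
  expect_equal(r, 0.7, tolerance = 0.15)
  r2 <- cor(cl$duration[pdIdx], amps[pdIdx, 2]) # uncoupled covariate
  expect_lt(abs(r2), 0.2)
})

test_that("score-level simulators have the advertised structure", {
  ts <- simulateComponentScores(nPd = 5, nControl = 4, nTrials = 6, d = 2, seed = 7)
  expect_equal(nrow(ts), 9 * 6)
  expect_named(ts, c("subject", "group", paste0("comp", 1:4)))
  agg <- aggregate(comp1 ~ group, ts, mean)
  expect_gt(agg$comp1[agg$group == "Control"], agg$comp1[agg$group == "PD"])
  sim <- simulateAssociationScores(nSubjects = 8, nTrials = 5, rho = 0.9, seed = 8)
  expect_equal(nrow(sim$trialScores), 40)
  expect_equal(nrow(sim$clinical), 8)
  m <- aggregate(score ~ subject, sim$trialScores, mean)
  expect_gt(cor(m$score, sim$clinical$outcome), 0.5)
})
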