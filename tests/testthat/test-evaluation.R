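test_that("trivially separated classes give zero LOOCV error at every level", {
  kte <- toFrequencies(buildCountMatrix(disjointSamples(), 2))
  cv <- loocvCV2(kte)
  expect_true(all(errorRates(cv) == 0))
  expect_equal(cv@nSamples, 4L)
  expect_error(
    loocvCV2(toFrequencies(buildCountMatrix(disjointSamples()[c(1, 3, 4)], 2))),
    "at least 2 samples")
})

test_that("CV2 results are reproducible and leakage-free", {
  ds <- generateDataset(tinySimConfig(rngSeed = 51, nPerClass = 4))
  kte <- toFrequencies(buildCountMatrix(ds$samples, 2))
  cv1 <- loocvCV2(kte)
  cv2 <- loocvCV2(kte)
  expect_identical(cv1@errorRates, cv2@errorRates)
  expect_identical(cv1@predictions, cv2@predictions)
  expect_true(all(errorRates(cv1) >= 0 & errorRates(cv1) <= 1))

  # no leakage: replacing the held-out sample's reads entirely leaves the
  # training-fold feature selection for that fold unchanged
  i <- 3L
  mutated <- ds$samples
  set.seed(99)
  mutated[[i]] <- ReadSet(sampleId(ds$samples[[i]]),
                          vapply(1:30, function(j) {
                            paste(sample(DNA4, 30, TRUE), collapse = "")
                          }, ""),
                          sampleLabel(ds$samples[[i]]))
  cvMut <- loocvCV2(toFrequencies(buildCountMatrix(mutated, 2)))
  expect_identical(cvMut@foldFeatures[[i]], cv1@foldFeatures[[i]])
})

test_that("the best-result rule follows the stated priority order", {
  # grid shaped like a published example: the 6-tuple run reaches error 0
  # from the 50-feature level down, and the overall winner is (k=6, 5 feats)
  lv3 <- c(64, 50, 30, 20, 10, 5)
  lv <- c(4^4, 1000, 500, 200, 100, 50, 30, 20, 10, 5)
  grid <- list(
    fakeCV2(3, lv3, c(0.16, 0.18, 0.28, 0.28, 0.28, NA)),
    fakeCV2(4, c(256, 200, 100, 50, 30, 20, 10, 5),
            c(0.14, 0.14, 0.18, 0.18, 0.24, 0.34, 0.40, NA)),
    fakeCV2(5, c(1024, lv[-1]),
            c(0.06, 0.06, 0.06, 0.08, 0.02, 0.02, 0.02, 0.00, 0.02, 0.12)),
    fakeCV2(6, c(4096, lv[-1]),
            c(0.04, 0.04, 0.04, 0.04, 0.02, 0.00, 0.00, 0.00, 0.00, 0.00)),
    fakeCV2(7, c(16384, lv[-1]),
            c(0.10, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.04, 0.04)),
    fakeCV2(8, c(65536, lv[-1]),
            c(0.26, 0.10, 0.10, 0.14, 0.28, 0.30, 0.40, 0.46, 0.42, 0.46)))
  best <- bestResult(grid)
  expect_equal(best@k, 6L)
  expect_equal(best@level, 5L)
  expect_equal(best@accuracy, 1.00)

  # the level cap excludes levels above 200 even at higher accuracy
  capped <- bestResult(list(
    fakeCV2(5, c(1024, 500, 200, 100), c(0.00, 0.00, 0.10, 0.15)),
    fakeCV2(6, c(4096, 500, 200, 100), c(0.20, 0.20, 0.15, 0.20))))
  expect_equal(capped@level, 200L)
  expect_equal(capped@k, 5L)
  expect_equal(capped@accuracy, 0.90)

  # tie cascade: equal accuracies -> smallest level, then smallest k
  tied <- bestResult(list(fakeCV2(5, c(30, 10), c(0.1, 0.1)),
                          fakeCV2(4, c(30, 10), c(0.1, 0.1))))
  expect_equal(tied@level, 10L)
  expect_equal(tied@k, 4L)

  single <- bestResult(fakeCV2(4, 20, 0.25))
  expect_equal(single@k, 4L)
  expect_equal(single@accuracy, 0.75)
  expect_error(bestResult(list()), "no results")
})

test_that("selecting features outside the folds is optimistically biased", {
  # on label-permuted (signal-free) data, the biased protocol (selection
  # on all samples, then cross-validation) beats the honest one on average
  ds <- generateDataset(tinySimConfig(rngSeed = 53, nPerClass = 5,
                                      nSeeds2 = 0))
  kte <- toFrequencies(buildCountMatrix(ds$samples, 3))
  y <- sampleLabels(kte)
  set.seed(54)
  diffs <- vapply(1:50, function(b) {
    yp <- permuteLabels(y)
    b1 <- bestResult(loocvCV1(kte, labels = yp))@accuracy
    b2 <- bestResult(loocvCV2(kte, labels = yp))@accuracy
    b1 - b2
  }, 0)
  expect_gt(mean(diffs), 0.05)
})

test_that("the final refit is deterministic and serializable", {
  ds <- generateDataset(tinySimConfig(rngSeed = 55, nPerClass = 4,
                                      density = 0.05))
  kte <- toFrequencies(buildCountMatrix(ds$samples, 3))
  f1 <- finalModel(kte, 10)
  f2 <- finalModel(kte, 10)
  expect_identical(f1@words, f2@words)
  expect_equal(length(f1@words), 10L)

  # level = full feature count trains on everything
  fAll <- finalModel(kte, 64)
  expect_equal(length(fAll@words), 64L)
  expect_error(finalModel(kte, 7), "not on the ladder")

  # training samples of a separable fit are classified perfectly
  pred <- predictSamples(f1, ds$samples)
  expect_equal(pred$predicted, sampleLabels(kte))
  perf <- attr(pred, "performance")
  expect_equal(unname(perf["accuracy"]), 1)
  expect_equal(unname(perf["sensitivity"]), 1)
  expect_equal(unname(perf["specificity"]), 1)

  # empty input gives an empty frame
  expect_equal(nrow(predictSamples(f1, list())), 0L)

  # JSON round trip preserves predictions exactly
  path <- withr::local_tempfile(fileext = ".json")
  writeModelJSON(f1, path)
  f1b <- readModelJSON(path)
  expect_identical(f1b@words, f1@words)
  predB <- predictSamples(f1b, ds$samples)
  expect_equal(predB$decision, pred$decision)
})

test_that("held-out samples from the same generator are classified near the LOOCV estimate", {
  cfg <- tinySimConfig(rngSeed = 56, nPerClass = 8, density = 0.05,
                       nSeeds2 = 2, seedLength = 5, coverage = 5)
  ds <- generateDataset(cfg)
  kte <- toFrequencies(buildCountMatrix(ds$samples, 5))
  cv <- loocvCV2(kte)
  best <- bestResult(cv)
  fm <- finalModel(kte, best@level)
  correct <- 0L; total <- 0L
  for (rep in 1:20) {
    cfgNew <- cfg
    cfgNew$rngSeed <- childSeed(56, paste0("test", rep))
    dsNew <- generateDataset(cfgNew)
    pred <- predictSamples(fm, dsNew$samples)
    correct <- correct + sum(pred$predicted == pred$label)
    total <- total + nrow(pred)
  }
  expect_gte(correct / total, best@accuracy - 0.1)
})

test_that("cv results tabulate with sensitivity and specificity", {
  kte <- toFrequencies(buildCountMatrix(disjointSamples(), 2))
  tab <- cvResultsTable(loocvCV2(kte))
  expect_named(tab, c("k", "level", "error_rate", "accuracy",
                      "sensitivity", "specificity"))
  expect_true(all(tab$accuracy == 1))
  expect_true(all(tab$sensitivity == 1) && all(tab$specificity == 1))
})
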