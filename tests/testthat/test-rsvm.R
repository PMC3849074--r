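test_that("linear SVM solves the symmetric two-point problem", {
  m <- trainLinearSVM(cbind(c(-1, 1)), c(-1, 1))
  expect_lt(abs(svmBias(m)), 1e-6)          # boundary at 0
  expect_equal(predict(m, cbind(-0.5)), -1L)
  expect_equal(predict(m, cbind(0.5)), 1L)
  expect_error(trainLinearSVM(cbind(c(1, 2)), c(1, 1)), "both classes")
})

test_that("separable data is fit perfectly and duplication leaves the model unchanged", {
  set.seed(41)
  x <- matrix(rnorm(30 * 6), 30, 6)
  y <- rep(c(-1L, 1L), 15)
  x[y == 1, 1] <- x[y == 1, 1] + 6
  m <- trainLinearSVM(x, y, cost = 100)
  expect_equal(predict(m, x), y)
  m2 <- trainLinearSVM(rbind(x, x), c(y, y), cost = 100)
  expect_equal(svmWeights(m2), svmWeights(m), tolerance = 1e-4)
  expect_equal(svmBias(m2), svmBias(m), tolerance = 1e-4)
})

test_that("dual coefficients reconstruct the primal weights", {
  set.seed(42)
  for (rep in 1:5) {
    p <- sample(c(5, 40, 300), 1)          # narrow and wide (p > n) cases
    x <- matrix(rnorm(24 * p), 24, p)
    y <- rep(c(-1L, 1L), 12)
    x[y == 1, 1:3] <- x[y == 1, 1:3] + 1
    m <- trainLinearSVM(x, y)
    expect_true(all(dualCoefs(m) >= 0))
    w2 <- drop(crossprod(x[m@svIndex, , drop = FALSE],
                         dualCoefs(m) * y[m@svIndex]))
    expect_equal(unname(w2), svmWeights(m), tolerance = 1e-6)
    # oriented correctly: decision values positive for class +1 on
    # comfortably separable points
    f <- predict(m, x, decision = TRUE)
    expect_gt(cor(f, y), 0.5)
  }
})

test_that("the decision function agrees with an independent solver", {
  skip_if_not_installed("kernlab")
  set.seed(43)
  x <- matrix(rnorm(30 * 20), 30, 20)
  y <- rep(c(-1L, 1L), 15)
  x[y == 1, 1:4] <- x[y == 1, 1:4] + 1.5
  m <- trainLinearSVM(x, y)
  fOur <- predict(m, x, decision = TRUE)
  fk <- kernlab::ksvm(x, y, type = "C-svc", kernel = "vanilladot", C = 1,
                      scaled = FALSE, tol = 1e-7)
  co <- unlist(kernlab::coef(fk)); idx <- unlist(kernlab::alphaindex(fk))
  fRef <- drop(x %*% crossprod(x[idx, , drop = FALSE], co)) - kernlab::b(fk)
  expect_equal(fOur, fRef, tolerance = 1e-3)
})

test_that("feature scores are the weight-weighted class-mean differences", {
  # closed-form case: w = (1, -1), class-mean differences (2, 2)
  m <- new("LinearSVMModel", weights = c(1, -1, 0), bias = 0,
           alpha = numeric(), svIndex = integer(),
           labels = c(-1L, 1L), featureSubset = 1:3, cost = 1)
  x3 <- rbind(c(2, 2, 5), c(2, 2, 7),    # class +1
              c(0, 0, 1), c(0, 0, 3))    # class -1
  y3 <- c(1L, 1L, -1L, -1L)
  expect_equal(featureScores(m, x3, y3), c(2, -2, 0))  # zero weight -> 0
  expect_error(featureScores(m, x3, rep(1L, 4)), "both classes")

  # oracle equivalence on random matrices
  set.seed(44)
  for (rep in 1:4) {
    x <- matrix(rnorm(10 * 8), 10, 8)
    y <- rep(c(1L, -1L), 5)
    mod <- trainLinearSVM(x, y)
    sOracle <- vapply(1:8, function(j) {
      mp <- sum(x[y == 1L, j]) / sum(y == 1L)
      mm <- sum(x[y == -1L, j]) / sum(y == -1L)
      svmWeights(mod)[j] * (mp - mm)
    }, 0)
    expect_equal(featureScores(mod, x, y), sOracle)
  }
})

test_that("the ladder truncates correctly for small feature spaces", {
  expect_equal(buildLadder(64), c(64L, 50L, 30L, 20L, 10L, 5L))
  expect_equal(buildLadder(4096),
               c(4096L, 1000L, 500L, 200L, 100L, 50L, 30L, 20L, 10L, 5L))
  expect_equal(buildLadder(1024),
               c(1024L, 1000L, 500L, 200L, 100L, 50L, 30L, 20L, 10L, 5L))
  expect_equal(buildLadder(5), 5L)
  expect_equal(buildLadder(256), c(256L, 200L, 100L, 50L, 30L, 20L, 10L, 5L))
  expect_error(buildLadder(0), "at least 1")
})

test_that("recursive selection nests subsets and recovers planted features", {
  set.seed(45)
  x <- matrix(rnorm(40 * 100), 40, 100)
  y <- rep(c(-1L, 1L), 20)
  x[y == 1, c(7, 61)] <- x[y == 1, c(7, 61)] + 3
  rs <- recursiveSelect(x, y, ladder = c(100L, 50L, 20L, 10L, 5L, 2L))
  expect_equal(ladderLevels(rs), c(100L, 50L, 20L, 10L, 5L, 2L))
  feats <- lapply(ladderLevels(rs), function(l) selectedFeatures(rs, l))
  for (j in 2:length(feats))
    expect_true(all(feats[[j]] %in% feats[[j - 1]]))
  expect_setequal(selectedFeatures(rs, 2), c(7L, 61L))

  # single-level ladder: no selection
  rs1 <- recursiveSelect(x, y, ladder = 100L)
  expect_equal(selectedFeatures(rs1, 100), 1:100)
})

test_that("selection is deterministic and equivariant to column permutation", {
  set.seed(46)
  x <- matrix(rnorm(30 * 60), 30, 60)
  y <- rep(c(-1L, 1L), 15)
  x[y == 1, 1:4] <- x[y == 1, 1:4] + 2
  ladder <- c(60L, 20L, 5L)
  a <- recursiveSelect(x, y, ladder)
  b <- recursiveSelect(x, y, ladder)
  expect_identical(a@features, b@features)

  perm <- sample(60)
  xp <- x[, perm]
  rp <- recursiveSelect(xp, y, ladder)
  for (j in seq_along(ladder))
    expect_setequal(perm[rp@features[[j]]], a@features[[j]])
})

test_that("planted features are recovered in at least 95% of seeded runs", {
  hits <- 0L
  for (run in 1:100) {
    set.seed(5000 + run)
    x <- matrix(rnorm(20 * 100), 20, 100)
    y <- rep(c(-1L, 1L), 10)
    x[y == 1, c(13, 77)] <- x[y == 1, c(13, 77)] + 3
    rs <- recursiveSelect(x, y, ladder = c(100L, 50L, 20L, 10L, 5L, 2L))
    if (setequal(selectedFeatures(rs, 2), c(13L, 77L))) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("prediction follows sign(w x + b) with zero mapped to +1", {
  m <- new("LinearSVMModel", weights = c(1, 0), bias = 0, alpha = numeric(),
           svIndex = integer(), labels = c(-1L, 1L), featureSubset = 1:2,
           cost = 1)
  expect_equal(predict(m, cbind(3, 9)), 1L)
  expect_equal(predict(m, cbind(-3, 9)), -1L)
  expect_equal(predict(m, cbind(0, 5)), 1L)   # exact tie -> +1
  expect_error(predict(m, cbind(1, 2, 3)), "columns")
})
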