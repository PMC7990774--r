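test_that("class covariance matches its definition in both modes", {
  # single trial with orthonormal rows -> pooled covariance is identity
  set.seed(1)
  Q <- qr.Q(qr(matrix(rnorm(20 * 4), 20, 4)))  # 4 orthonormal columns
  X <- t(Q)                                    # 4 channels x 20 samples
  es <- EpochSet(array(X, c(1, 4, 20)), 1L, paste0("C", 1:4), 100)
  cc <- classCovariance(es, mode = "pooled")
  expect_equal(cc$matrix, diag(4), tolerance = 1e-12)

  # duplication doubles pooled, leaves trace-normalized unchanged
  es1 <- toyEpochs(nPerClass = 3, seed = 2)
  es2 <- es1[c(seq_len(6), seq_len(6))]
  expect_equal(classCovariance(es2, "pooled")$matrix,
               2 * classCovariance(es1, "pooled")$matrix)
  expect_equal(classCovariance(es2, "averaged")$matrix,
               classCovariance(es1, "averaged")$matrix)
})

test_that("pooled covariance equals the naive double loop over channels", {
  es <- toyEpochs(nPerClass = 2, seed = 3, nSamples = 15)
  got <- classCovariance(es, "pooled")$matrix
  C <- nChannels(es)
  naive <- matrix(0, C, C)
  for (i in seq_len(nTrials(es)))
    for (a in seq_len(C)) for (b in seq_len(C))
      naive[a, b] <- naive[a, b] +
        sum(epochData(es)[i, a, ] * epochData(es)[i, b, ])
  expect_equal(got, naive, tolerance = 1e-10)
})

test_that("diagonal covariances give the analytic CSP solution", {
  bank <- fitCsp(diag(c(2, 1)), diag(c(1, 2)), k = 1L, reg = 0)
  W <- cspFilters(bank)
  ev <- cspEigenvalues(bank)
  expect_equal(ev, c(2, 2), tolerance = 1e-12)
  # class-1 filter along axis 1, normalized so w'C2w = 1
  expect_equal(abs(W[, 1]), c(1, 0), tolerance = 1e-10)
  expect_equal(abs(W[, 2]), c(0, 1), tolerance = 1e-10)
  expect_error(fitCsp(diag(2), diag(2), k = 2L), "2k")
})

test_that("the variance-ratio objective is scale invariant", {
  C1 <- randomSPD(5, 10); C2 <- randomSPD(5, 11)
  w <- rnorm(5)
  expect_equal(cspObjective(3 * w, C1, C2), cspObjective(w, C1, C2),
               tolerance = 1e-12)
})

test_that("filters satisfy their unit-variance constraints to 1e-8", {
  for (seed in 1:5) {
    C1 <- randomSPD(8, seed); C2 <- randomSPD(8, seed + 50)
    reg <- 1e-6
    bank <- fitCsp(C1, C2, k = 3L, reg = reg)
    W <- cspFilters(bank)
    r1 <- C2 + reg * mean(diag(C2)) * diag(8)
    r2 <- C1 + reg * mean(diag(C1)) * diag(8)
    for (j in 1:3)
      expect_equal(drop(crossprod(W[, j], r1 %*% W[, j])), 1,
                   tolerance = 1e-8)
    for (j in 4:6)
      expect_equal(drop(crossprod(W[, j], r2 %*% W[, j])), 1,
                   tolerance = 1e-8)
    # eigenvalue residual: C1 w = lambda C2 w for the class-1 block
    ev <- cspEigenvalues(bank)
    for (j in 1:3) {
      res <- C1 %*% W[, j] - ev[j] * (r1 %*% W[, j])
      expect_lt(sqrt(sum(res^2)), 1e-6 * sqrt(sum((C1 %*% W[, j])^2)))
    }
    # descending within each block; swapped eigenvalues ~ 1/smallest
    expect_false(is.unsorted(rev(ev[1:3])))
    expect_false(is.unsorted(rev(ev[4:6])))
  }
})

test_that("the class-2 block solves the swapped problem", {
  C1 <- randomSPD(6, 70); C2 <- randomSPD(6, 71)
  bank <- fitCsp(C1, C2, k = 3L)
  swapped <- fitCsp(C2, C1, k = 3L)
  expect_equal(cspFilters(bank)[, 4:6], cspFilters(swapped)[, 1:3],
               tolerance = 1e-9)
  expect_equal(cspEigenvalues(bank)[4:6], cspEigenvalues(swapped)[1:3],
               tolerance = 1e-10)
})

test_that("non-PSD or asymmetric inputs are rejected", {
  bad <- matrix(c(1, 2, 0, 1), 2)
  expect_error(fitCsp(bad, diag(2), k = 1L), "symmetric")
  neg <- diag(c(1, -1))
  expect_error(fitCsp(neg, diag(2), k = 1L), "positive semidefinite")
  expect_error(fitCsp(diag(3), diag(2), k = 1L), "equal dimensions")
})

test_that("log normalized-variance features behave as defined", {
  es <- toyEpochs(nPerClass = 4, seed = 5)
  c1 <- classCovariance(es[trialLabels(es) == 1])
  c2 <- classCovariance(es[trialLabels(es) == 2])
  bank <- fitCsp(c1, c2, k = 2L, channelNames = channelNames(es))
  f <- cspFeatures(es, bank)
  expect_equal(dim(f), c(8, 4))
  # normalization: exp(features) sums to one per trial
  expect_equal(rowSums(exp(f)), rep(1, 8), tolerance = 1e-10)
  # amplitude invariance
  es2 <- es; es2@data <- 2 * es@data
  expect_equal(cspFeatures(es2, bank), f, tolerance = 1e-10)
  # a pure source along filter 1's direction maximizes feature 1:
  # build a trial whose rows follow the pattern a1 = C2reg w1 (the
  # forward model of filter 1), for which w' x is largest for w1
  W <- cspFilters(bank)
  r1 <- c2$matrix + 1e-6 * mean(diag(c2$matrix)) * diag(4)
  a1 <- drop(r1 %*% W[, 1])
  s <- sin(2 * pi * 10 * seq_len(20) / 100)
  pure <- EpochSet(array(a1 %o% s, c(1, 4, 20)), 1L, channelNames(es), 100,
                   classNames = c("a", "b"))
  fp <- cspFeatures(pure, bank)
  expect_equal(unname(which.max(fp[1, ])), 1L)
  expect_error(cspFeatures(toyEpochs(channels = c("C3", "C4")), bank),
               "channels")
})

test_that("CSP-SVM separates strongly lateralized synthetic data", {
  sub <- simulateSubject(synthParams(nTrialsPerClass = 40, seed = 41))
  st <- splitTrainTest(sub$epochs, nTrain = 40, seed = 1)
  clf <- cspSvmClassifier()
  state <- fitClassifier(clf, st$train)
  acc <- mean(predictClassifier(clf, state, st$test) ==
                trialLabels(st$test))
  expect_gt(acc, 0.9)
  expect_error(fitClassifier(clf, st$train[trialLabels(st$train) == 1]),
               "single class")
})

test_that("permuted labels give chance-level cross-validated accuracy", {
  sub <- simulateSubject(synthParams(nTrialsPerClass = 50, seed = 43))
  es <- sub$epochs
  set.seed(4)
  es@labels <- sample(es@labels)  # break the label-signal link
  st <- splitTrainTest(es, nTrain = 50, seed = 2)
  clf <- cspSvmClassifier()
  state <- fitClassifier(clf, st$train)
  acc <- mean(predictClassifier(clf, state, st$test) ==
                trialLabels(st$test))
  nTest <- nTrials(st$test)
  halfWidth <- 2.576 * sqrt(0.25 / nTest)
  expect_gt(acc, 0.5 - halfWidth)
  expect_lt(acc, 0.5 + halfWidth)
})
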