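# Losses, network fitting, encode/reconstruct contracts, and the
# objective-equivalence and monotonicity properties.

test_that("reconstruction loss matches elementwise enumeration", {
  expect_equal(reconstructionLoss(matrix(1:4, 2), matrix(1:4, 2)), 0)
  expect_equal(reconstructionLoss(matrix(0, 2, 2), matrix(1, 2, 2)), 1)
  X <- matrix(c(1, 3, 2, 4), 2); Xh <- matrix(c(1, 0, 0, 4), 2)
  expect_equal(reconstructionLoss(X, Xh), 3.25)
  expect_equal(reconstructionLoss(X, Xh), bruteMSE(X, Xh), tolerance = 1e-15)
  expect_equal(reconstructionLoss(X, Xh), reconstructionLoss(Xh, X))
  expect_error(reconstructionLoss(X, matrix(0, 3, 2)), "shape")
})

test_that("cross-entropy matches closed forms and is clipped, not infinite", {
  Y <- diag(2)
  expect_equal(crossEntropyLoss(Y, Y + c(1e-13, -1e-13)), 0,
               tolerance = 1e-10)
  k <- 10
  Yk <- diag(k)
  expect_equal(crossEntropyLoss(Yk, matrix(1 / k, k, k)), log(10))
  y1 <- matrix(c(1, 0), 1); p1 <- matrix(c(0.8, 0.2), 1)
  expect_equal(crossEntropyLoss(y1, p1), -log(0.8))
  expect_equal(crossEntropyLoss(y1, p1), bruteCrossEntropy(y1, p1),
               tolerance = 1e-15)
  # probability exactly 0 at the true class: finite by clipping
  expect_true(is.finite(crossEntropyLoss(matrix(c(1, 0), 1),
                                         matrix(c(0, 1), 1))))
  expect_error(crossEntropyLoss(y1, matrix(c(0.8, 0.9), 1)), "sum to 1")
})

test_that("the joint objective is the weighted sum of its two parts", {
  X <- matrix(c(1, 3, 2, 4), 2); Xh <- matrix(c(1, 0, 0, 4), 2)
  Y <- matrix(c(1, 0, 0, 1), 2); P <- matrix(c(0.8, 0.3, 0.2, 0.7), 2)
  expect_equal(traceObjective(X, Xh, Y, P, alpha = 0),
               reconstructionLoss(X, Xh))
  expect_equal(traceObjective(X, X, Y, Y * 0.9999998 + 1e-7, alpha = 3), 0,
               tolerance = 1e-6)
  y1 <- matrix(c(1, 0), 1); p1 <- matrix(c(0.8, 0.2), 1)
  expect_equal(traceObjective(X, Xh, y1, p1, alpha = 2),
               3.25 + 2 * (-log(0.8)))
  expect_error(traceObjective(X, Xh, Y, P, alpha = -1), "alpha")
})

test_that("PCA at full rank reconstructs losslessly and encodes invertibly", {
  ds <- makeToyData(k = 3L, n = 12L, perClass = 10L)
  # rank-5 data: prototypes from 3 classes + rank-0 nuisance + no noise
  low <- generateSynthetic(3, 12, 10, noiseSd = 0, irrelevantScale = 1,
                           irrelevantRank = 2, seed = 4)
  X <- features(low$train)
  r <- qr(scale(X, scale = FALSE))$rank
  m <- fitModel(modelConfig("PCA", 12, r), low$train)
  expect_lt(reconstructionLoss(X, reconstruct(m, X)), 1e-10)
  mFull <- fitModel(modelConfig("PCA", 12, 12), ds$train)
  Xt <- features(ds$train)
  expect_lt(max(abs(reconstruct(mFull, Xt) - Xt)), 1e-8)
})

test_that("PCA reconstruction loss is non-increasing in bottleneck width", {
  ds <- makeToyData(k = 3L, n = 20L, perClass = 15L)
  X <- features(ds$train)
  losses <- vapply(c(1L, 2L, 5L, 10L, 20L), function(d) {
    m <- fitModel(modelConfig("PCA", 20, d), ds$train)
    reconstructionLoss(X, reconstruct(m, X))
  }, numeric(1))
  expect_true(all(diff(losses) <= 1e-10))
})

test_that("TRACE with alpha = 0 reproduces AE's loss trace bit-for-bit", {
  ds <- makeToyData(k = 3L, n = 30L, perClass = 20L)
  cfgT <- modelConfig("TRACE", 30, 3, classCount = 3, alpha = 0,
                      epochs = 12, seed = 17)
  cfgA <- modelConfig("AE", 30, 3, epochs = 12, seed = 17)
  mT <- fitModel(cfgT, ds$train)
  mA <- fitModel(cfgA, ds$train)
  expect_identical(mT@lossTrace, mA@lossTrace)
  # shared weights identical too
  for (nm in c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4"))
    expect_identical(mT@params[[nm]], mA@params[[nm]])
})

test_that("fitting is reproducible under a fixed seed", {
  ds <- makeToyData(k = 3L, n = 20L, perClass = 10L)
  cfg <- modelConfig("VAE", 20, 2, epochs = 8, seed = 23)
  m1 <- fitModel(cfg, ds$train)
  m2 <- fitModel(cfg, ds$train)
  expect_identical(m1@params, m2@params)
  expect_identical(m1@lossTrace, m2@lossTrace)
})

test_that("training loss decreases and stays finite on the toy fixture", {
  ds <- makeToyData(k = 3L, n = 30L, perClass = 20L)
  for (fam in c("TRACE", "AE", "VAE")) {
    cfg <- modelConfig(fam, 30, 3, classCount = 3, epochs = 30, seed = 5)
    m <- fitModel(cfg, ds$train)
    lt <- m@lossTrace
    expect_true(all(is.finite(lt)))
    expect_lt(lt[length(lt)], lt[1])
  }
})

test_that("a hand-set scalar network reproduces the tanh forward chain", {
  cfg <- modelConfig("AE", 1, 1, hiddenDim = 1, epochs = 1, seed = 1)
  m <- fitModel(cfg, LabeledMatrix(matrix(c(0.1, -0.2)), c(0, 1)))
  m@params <- list(W1 = matrix(0.5), b1 = 0.1, W2 = matrix(2), b2 = -0.3,
                   W3 = matrix(1.5), b3 = 0.2, W4 = matrix(-0.7), b4 = 0.4)
  x <- 0.8
  z <- tanh(x * 0.5 + 0.1) * 2 - 0.3
  xhat <- tanh(z * 1.5 + 0.2) * (-0.7) + 0.4
  expect_equal(encode(m, matrix(x))[1, 1], z, tolerance = 1e-15)
  expect_equal(reconstruct(m, matrix(x))[1, 1], xhat, tolerance = 1e-15)
})

test_that("all-zero weights propagate to an all-zero bottleneck", {
  cfg <- modelConfig("AE", 4, 2, hiddenDim = 3, epochs = 1, seed = 1)
  ds <- makeToyData(k = 2L, n = 4L, perClass = 4L)
  m <- fitModel(cfg, ds$train)
  m@params <- lapply(m@params, function(w) w * 0)
  expect_equal(encode(m, matrix(rnorm(8), 2)), matrix(0, 2, 2))
})

test_that("encode/reconstruct validate input width and output shapes", {
  ds <- makeToyData(k = 3L, n = 20L, perClass = 10L)
  m <- fitModel(modelConfig("TRACE", 20, 4, classCount = 3, epochs = 3,
                            seed = 2), ds$train)
  Z <- encode(m, ds$test)
  expect_equal(ncol(Z), 4L)
  R <- reconstruct(m, ds$test)
  expect_equal(dim(R), dim(features(ds$test)))
  expect_error(encode(m, matrix(0, 2, 7)), "columns")
  P <- classProbabilities(m, ds$test)
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-12)
})

test_that("gradient of the joint objective matches finite differences", {
  # small-network numeric check of the hand-derived backward pass
  set.seed(31)
  X <- matrix(rnorm(5 * 6), 5, 6)
  y <- c(0L, 1L, 2L, 0L, 1L)
  cfg <- modelConfig("TRACE", 6, 2, classCount = 3, hiddenDim = 4,
                     alpha = 0.7, epochs = 1, seed = 3)
  p <- TRACEkit:::.initParams(cfg)
  Y <- TRACEkit:::.onehot(y, 3L)
  g <- TRACEkit:::.gradAEBatch(p, X, Y, cfg, TRUE)
  lossAt <- function(pp) TRACEkit:::.fullLoss(pp, X, Y, cfg)
  for (nm in c("W1", "W2", "Wc", "W4", "b2")) {
    w <- p[[nm]]
    i <- if (is.matrix(w)) c(1L, 1L) else 1L
    h <- 1e-6
    pp <- p
    if (is.matrix(w)) pp[[nm]][1, 1] <- w[1, 1] + h else
      pp[[nm]][1] <- w[1] + h
    pm <- p
    if (is.matrix(w)) pm[[nm]][1, 1] <- w[1, 1] - h else
      pm[[nm]][1] <- w[1] - h
    num <- (lossAt(pp) - lossAt(pm)) / (2 * h)
    ana <- if (is.matrix(w)) g[[nm]][1, 1] else g[[nm]][1]
    expect_equal(ana, num, tolerance = 1e-5)
  }
})

test_that("VAE gradient matches finite differences", {
  set.seed(33)
  X <- matrix(rnorm(4 * 5), 4, 5)
  cfg <- modelConfig("VAE", 5, 2, hiddenDim = 3, epochs = 1, seed = 3)
  p <- TRACEkit:::.initParams(cfg)
  eps <- matrix(rnorm(8), 4, 2)
  g <- TRACEkit:::.gradVAEBatch(p, X, cfg, eps)
  lossAt <- function(pp) {
    H1 <- tanh(TRACEkit:::.addBias(X %*% pp$W1, pp$b1))
    Mu <- TRACEkit:::.addBias(H1 %*% pp$W2, pp$b2)
    Lv <- TRACEkit:::.addBias(H1 %*% pp$W2lv, pp$b2lv)
    Z <- Mu + exp(0.5 * Lv) * eps
    H2 <- tanh(TRACEkit:::.addBias(Z %*% pp$W3, pp$b3))
    Xh <- TRACEkit:::.addBias(H2 %*% pp$W4, pp$b4)
    kl <- 0.5 * sum(exp(Lv) + Mu^2 - 1 - Lv)
    mean((Xh - X)^2) + cfg@klWeight * kl / (nrow(X) * ncol(X))
  }
  for (nm in c("W1", "W2", "W2lv", "W3")) {
    h <- 1e-6
    pp <- p; pp[[nm]][1, 1] <- p[[nm]][1, 1] + h
    pm <- p; pm[[nm]][1, 1] <- p[[nm]][1, 1] - h
    num <- (lossAt(pp) - lossAt(pm)) / (2 * h)
    expect_equal(g[[nm]][1, 1], num, tolerance = 1e-5)
  }
})

test_that("models serialize to text and reload without retraining", {
  ds <- makeToyData(k = 3L, n = 10L, perClass = 6L)
  dir <- withr::local_tempdir()
  for (fam in c("TRACE", "PCA")) {
    m <- fitModel(modelConfig(fam, 10, 2, classCount = 3, epochs = 3,
                              seed = 9), ds$train)
    path <- file.path(dir, paste0(fam, ".json"))
    saveModel(m, path)
    m2 <- loadModel(path)
    expect_equal(encode(m2, ds$test), encode(m, ds$test),
                 tolerance = 1e-12)
    expect_equal(reconstruct(m2, ds$test), reconstruct(m, ds$test),
                 tolerance = 1e-12)
  }
})
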