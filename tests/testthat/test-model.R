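# CNN construction, standardization, training mechanics, ablation.

test_that("standardization uses training statistics with the population SD", {
  X <- matrix(c(0, 2, 5, 5, 1, 3), nrow = 2L)
  s <- fitStandardizer(X)
  Z <- applyStandardizer(s, X)
  expect_equal(Z[, 1L], c(-1, 1))            # population SD of (0,2) is 1
  expect_identical(Z[, 2L], c(0, 0))         # constant column -> zeros
  expect_equal(colMeans(Z), c(0, 0, 0), tolerance = 1e-12)
  # validation rows reuse the training statistics, never refit
  Xv <- matrix(c(4, 6, 5, 9, 2, 2), nrow = 2L)
  Zv <- applyStandardizer(s, Xv)
  expect_equal(Zv[, 1L], c(3, 5))            # (x - 1)/1 with training stats
  expect_identical(Zv[, 2L], c(0, 0))
  expect_error(fitStandardizer(X[1L, , drop = FALSE]), "at least 2")
  expect_error(applyStandardizer(s, Xv[, 1:2]), "does not match")
})

test_that("standardized training columns have zero mean and unit spread", {
  set.seed(71)
  X <- matrix(rpois(200 * 30, 2), 200L)
  Z <- applyStandardizer(fitStandardizer(X), X)
  live <- apply(X, 2L, var) > 0
  expect_lt(max(abs(colMeans(Z))), 1e-9)
  popSd <- sqrt(colMeans(Z^2) - colMeans(Z)^2)
  expect_equal(unname(popSd[live]), rep(1, sum(live)), tolerance = 1e-9)
})

test_that("model building is seed-deterministic with the published layout", {
  cfg <- trainConfig()
  expect_identical(cfg@convFilters, c(32L, 64L, 128L))
  expect_identical(cfg@kernelSize, 4L)
  expect_identical(cfg@stride, 1L)
  expect_identical(cfg@fcWidths, c(100L, 50L))
  expect_identical(cfg@learningRate, 0.001)
  expect_identical(cfg@l2Weight, 0.01)
  expect_identical(cfg@batchSize, 64L)
  expect_identical(cfg@alpha, 0.7)
  expect_identical(cfg@patience, 20L)
  expect_identical(cfg@minDelta, 0.001)
  expect_identical(cfg@nRuns, 5L)
  m1 <- buildModel(c(62L, 168L), cfg, seed = 5L)
  m2 <- buildModel(c(62L, 168L), cfg, seed = 5L)
  expect_identical(m1@params, m2@params)
  expect_length(m1@params$conv, 3L)
  expect_identical(vapply(m1@params$conv, function(l) nrow(l$W), 0L),
                   c(32L, 64L, 128L))
  m3 <- buildModel(c(62L, 168L), cfg, seed = 6L)
  expect_false(identical(m1@params$conv[[1L]]$W, m3@params$conv[[1L]]$W))
})

test_that("parameter count matches the layer-by-layer arithmetic", {
  cfg <- trainConfig()
  m <- buildModel(c(62L, 168L), cfg)
  # valid padding: 62x168 -> 59x165 -> 56x162 -> 53x159
  flat <- 128L * 53L * 159L
  hand <- (32 * 4 * 4 * 1 + 32) + (64 * 4 * 4 * 32 + 64) +
    (128 * 4 * 4 * 64 + 128) +
    (100 * flat + 100 + 2 * 100) + (50 * 100 + 50 + 2 * 50) + (1 * 50 + 1)
  expect_identical(countParameters(m), as.integer(hand))
  # too-small input under valid padding is a configuration error
  expect_error(buildModel(c(5L, 168L), cfg), "receptive field")
})

test_that("compiled convolution kernels agree with the R reference path", {
  set.seed(72)
  for (padding in c("valid", "same")) {
    plan <- shellscore:::.convPlan(7L, 11L, 2L, 3L, 1L, padding)
    X <- matrix(rnorm(7 * 11 * 2 * 5), ncol = 5L)
    W <- matrix(rnorm(4 * 18), 4L)
    b <- rnorm(4)
    fC <- shellscore:::.convForward(X, W, b, plan)
    fR <- shellscore:::.convForwardR(X, W, b, plan)
    expect_equal(fC, fR, tolerance = 1e-12)
    dOut <- matrix(rnorm(length(fC)), nrow(fC))
    gC <- shellscore:::.convBackward(X, W, plan, dOut)
    gR <- shellscore:::.convBackwardR(X, W, plan, dOut)
    expect_equal(gC$dW, gR$dW, tolerance = 1e-12)
    expect_equal(gC$db, as.numeric(gR$db), tolerance = 1e-12)
    expect_equal(gC$dX, gR$dX, tolerance = 1e-12)
  }
})

test_that("early stopping triggers at the patience-th flat epoch", {
  # improving run never triggers
  expect_true(is.na(earlyStopEpoch(seq(2, 0.5, by = -0.1), patience = 5L)))
  # flat within minDelta for exactly `patience` epochs after the best
  losses <- c(1, 0.5, rep(0.4995, 20L))
  expect_identical(earlyStopEpoch(losses, patience = 20L, minDelta = 0.001),
                   22L)
  # a real improvement resets the counter
  losses2 <- c(1, 0.5, rep(0.4995, 10L), 0.4, rep(0.3995, 19L), 0.3999)
  expect_identical(earlyStopEpoch(losses2, patience = 20L, minDelta = 0.001),
                   33L)
})

test_that("ensemble mean equals an independent member-wise average", {
  d <- smallLinearDataset()
  X <- d$ds$features
  y <- d$ds$pkd
  cfg <- recoveryConfig(301L, nRuns = 3L)
  cfg@maxEpochs <- 6L
  ens <- trainEnsemble(X[1:300, ], y[1:300], X[301:400, ], y[301:400],
                       config = cfg)
  pr <- ensemblePredict(ens, X[301:400, ])
  # recomputation oracle: loop the members by hand
  Z <- applyStandardizer(ens@standardizer, X[301:400, ])
  manual <- rep(0, 100L)
  for (m in ens@members) manual <- manual + predict(m, Z)
  expect_equal(pr$mean, manual / 3, tolerance = 1e-12)
  expect_identical(dim(pr$members), c(100L, 3L))
  expect_true(all(is.finite(pr$sd)))
  # an ensemble of one is its single member
  one <- new("ShellCNNEnsemble", members = ens@members[1L],
             standardizer = ens@standardizer, config = cfg,
             inputDim = ens@inputDim)
  expect_identical(ensemblePredict(one, X[301:400, ])$mean,
                   predict(ens@members[[1L]], Z))
})

test_that("training is seed-reproducible end to end", {
  d <- smallLinearDataset()
  X <- d$ds$features
  y <- d$ds$pkd
  std <- fitStandardizer(X[1:300, ])
  Ztr <- applyStandardizer(std, X[1:300, ])
  Zva <- applyStandardizer(std, X[301:400, ])
  cfg <- recoveryConfig(88L)
  cfg@maxEpochs <- 5L
  m1 <- trainModel(buildModel(c(10L, 168L), cfg, seed = 88L),
                   Ztr, y[1:300], Zva, y[301:400], seed = 88L)
  m2 <- trainModel(buildModel(c(10L, 168L), cfg, seed = 88L),
                   Ztr, y[1:300], Zva, y[301:400], seed = 88L)
  expect_identical(predict(m1, Zva), predict(m2, Zva))
  expect_identical(m1@history, m2@history)
})

test_that("the returned checkpoint reproduces its minimum validation loss", {
  d <- smallLinearDataset()
  X <- d$ds$features
  y <- d$ds$pkd
  std <- fitStandardizer(X[1:300, ])
  Ztr <- applyStandardizer(std, X[1:300, ])
  Zva <- applyStandardizer(std, X[301:400, ])
  cfg <- recoveryConfig(89L)
  cfg@maxEpochs <- 12L
  m <- trainModel(buildModel(c(10L, 168L), cfg, seed = 89L),
                  Ztr, y[1:300], Zva, y[301:400], seed = 89L)
  reval <- shellscore:::.safeCompositeLoss(predict(m, Zva), y[301:400],
                                           cfg@alpha)
  expect_equal(reval, min(m@history$valLoss), tolerance = 1e-9)
})

test_that("a small model memorises 32 complexes (capacity check)", {
  d <- smallLinearDataset()
  X <- d$ds$features[1:32, ]
  y <- d$ds$pkd[1:32]
  std <- fitStandardizer(X)
  Z <- applyStandardizer(std, X)
  cfg <- trainConfig(convFilters = c(4L, 8L, 16L), fcWidths = c(32L, 16L),
                     learningRate = 0.02, batchSize = 32L,
                     maxEpochs = 500L, patience = 500L, minDelta = 0,
                     seedBase = 91L)
  m <- trainModel(buildModel(c(10L, 168L), cfg, seed = 91L), Z, y, Z, y,
                  seed = 91L)
  expect_lt(rmse(predict(m, Z), y), 0.1)
})

test_that("ablating a combination removes its column from every shell", {
  spec <- shellSpec(nShells = 62L)
  X <- matrix(0L, 3L, 10416L,
              dimnames = list(NULL, featureNames(spec)))
  X[, "7_CYS_H"] <- 5L
  red <- ablateCombination(X, spec, "CYS_H")
  expect_identical(ncol(red), 10354L)            # 62 x 167
  expect_identical(attr(red, "imageWidth"), 167L)
  expect_false(any(grepl("_CYS_H$", colnames(red))))
  expect_identical(sum(red), 0L)                 # the 5s sat in CYS_H
  # conservation: totals drop exactly by the removed combination's totals
  set.seed(92)
  X2 <- matrix(rpois(2 * 10416L, 0.2), 2L,
               dimnames = list(NULL, featureNames(spec)))
  red2 <- ablateCombination(X2, spec, c("ASN", "HAL"))
  expect_identical(rowSums(X2) - rowSums(red2),
                   rowSums(X2[, grepl("_ASN_HAL$", colnames(X2)),
                              drop = FALSE]))
  expect_error(ablateCombination(X2, spec, "FOO_C"), "unknown combination")
  # every one of the 168 ablations removes exactly N columns
  combos <- as.vector(t(outer(residueClasses(), ligandAtomClasses(),
                              paste, sep = "_")))
  widths <- vapply(combos[c(1, 60, 168)], function(cb)
    ncol(ablateCombination(X2, spec, cb)), 0L)
  expect_true(all(widths == 10354L))
})

test_that("a non-finite loss aborts with diagnostics", {
  d <- smallLinearDataset()
  X <- d$ds$features[1:64, ]
  y <- d$ds$pkd[1:64]
  Z <- applyStandardizer(fitStandardizer(X), X)
  Z[3L, 7L] <- Inf                      # corrupt one cell
  cfg <- trainConfig(convFilters = c(4L, 8L, 16L), fcWidths = c(32L, 16L),
                     learningRate = 0.02, batchSize = 64L, maxEpochs = 5L,
                     seedBase = 93L)
  expect_error(trainModel(buildModel(c(10L, 168L), cfg, seed = 93L),
                          Z, y, Z, y, seed = 93L),
               "learning rate|NaN")
})
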