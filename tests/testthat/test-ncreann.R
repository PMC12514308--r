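test_that("contrast trials subtract the standard mean exactly", {
  set.seed(1)
  dat <- array(rnorm(12 * 2 * 60), c(12, 2, 60))
  cond <- rep(c("standard", "deviant"), 6)
  ep <- makeEpochSet(dat, condition = cond, labels = c("A", "B"),
                     gridXY = matrix(0, 2, 2))
  ct <- contrastTrials(ep)
  stdMean <- apply(dat[cond == "standard", , ], c(2, 3), mean)
  expect_equal(dim(epochData(ct))[1], 6)
  expect_equal(epochData(ct)[1, , ], dat[2, , ] - stdMean)
  ## mean of contrast trials == deviant mean - standard mean
  devMean <- apply(dat[cond == "deviant", , ], c(2, 3), mean)
  expect_equal(apply(epochData(ct), c(2, 3), mean), devMean - stdMean)
  ## standards all zero: contrast equals the deviant trial
  dat0 <- dat
  dat0[cond == "standard", , ] <- 0
  ct0 <- contrastTrials(makeEpochSet(dat0, condition = cond,
                                     labels = c("A", "B"),
                                     gridXY = matrix(0, 2, 2)))
  expect_equal(epochData(ct0)[3, , ], dat0[6, , ])
  ep2 <- ep
  ep2@kept[cond == "deviant"] <- FALSE
  expect_error(contrastTrials(ep2), "deviant")
})

test_that("training rows count, standardise and split as documented", {
  set.seed(2)
  x <- matrix(rnorm(2 * 200, mean = 3, sd = 2), 2, 200)
  ct <- seriesContrast(x, 100)                  # 2 trials x 100 samples
  td <- buildTrainingData(ct, p = 8, seed = 1)
  expect_equal(nrow(td@X), (100 - 8) * 2)       # 184 target rows
  expect_equal(ncol(td@X), 2 * 8)
  ## z-scored channels
  expect_lt(abs(mean(td@Y)), 0.15)
  expect_equal(sd(as.vector(td@Y[, 1])), 1, tolerance = 0.15)
  ## x_p ordering: column (k-1)*M + i holds channel i at lag k
  z <- (x - rowMeans(x)) / apply(x, 1, sd)
  expect_equal(td@X[1, 1], z[1, 8], tolerance = 0.02)
  ## folds partition rows 80/10/10 and are seed-reproducible
  f <- td@folds[[1]]
  expect_equal(sort(c(f$train, f$val, f$test)), seq_len(184))
  expect_equal(length(f$train), floor(0.8 * 184))
  td2 <- buildTrainingData(ct, p = 8, seed = 1)
  expect_identical(td@folds, td2@folds)
  expect_error(buildTrainingData(ct, p = 100), "trial length")
})

test_that("information criteria recover the true linear order", {
  hits <- 0
  for (s in 1:5) {
    A <- ncreann:::randomStableVar(4, 3, seed = s, density = 0.4, scale = 0.35)
    x <- simulateNmvar(nmvarSpec(4, 3, A), 12000, seed = s + 50)
    os <- selectModelOrder(seriesContrast(x, 12000), pMax = 5)
    expect_true(all(is.finite(os@table$aic)) && all(is.finite(os@table$bic)))
    if (chosenOrder(os) == 3) hits <- hits + 1
  }
  expect_gte(hits, 4)
  ## white noise: order 1 (no structure beyond the first candidate)
  xw <- simulateNmvar(nmvarSpec(3, 1), 10000, seed = 9)
  expect_equal(chosenOrder(selectModelOrder(seriesContrast(xw, 10000),
                                            pMax = 4)), 1L)
})

test_that("the network recovers a realizable function almost exactly", {
  set.seed(42)
  N <- 5000; D <- 8; H <- 10; M <- 2
  X <- matrix(rnorm(N * D), N, D)
  W1 <- matrix(runif(H * D, -0.5, 0.5), H, D)
  W2 <- matrix(runif(M * H, -1, 1), M, H)
  Y <- t(W2 %*% tanh(W1 %*% t(X) + runif(H, -0.2, 0.2)) + runif(M, -0.2, 0.2))
  td <- new("TrainingData",
    X = X, Y = Y, segId = rep(1L, N),
    folds = list(list(train = 1:4000, val = 4001:4500, test = 4501:5000)),
    center = numeric(M), scale = numeric(M),
    M = as.integer(M), p = as.integer(D / M)
  )
  net <- trainNetwork(td, connectivityConfig(nReps = 1, maxEpochs = 150,
                                             patience = 10), seed = 7)
  d <- netDiagnostics(net)
  expect_lt(d$mseTest, 0.01 * mean(apply(Y, 2, var)))
  expect_gt(d$r2Test, 0.99)
})

test_that("on linear VAR data the network matches the linear fit's R2", {
  A <- ncreann:::randomStableVar(3, 2, seed = 4, density = 0.6, scale = 0.4)
  x <- simulateNmvar(nmvarSpec(3, 2, A), 12000, seed = 13)
  td <- buildTrainingData(seriesContrast(x, 12000), p = 2, seed = 1,
                          nReps = 2)
  net <- trainNetwork(td, fastConfig(p = 2, maxEpochs = 120, patience = 15,
                                     eta0 = 0.002), seed = 3)
  d <- netDiagnostics(net)
  ## least-squares linear oracle on the same rows
  fit <- lm.fit(cbind(1, td@X), td@Y)
  r2lin <- 1 - sum(fit$residuals^2) /
    sum(sweep(td@Y, 2, colMeans(td@Y), "-")^2)
  expect_lt(abs(median(d$r2Test) - r2lin), 0.05)
  ## healthy run: test error within 1.5x of training error
  expect_true(all(d$mseTest < 1.5 * d$mseTrain))
})

test_that("zero input weights give zero connectivity everywhere", {
  td <- new("TrainingData",
    X = matrix(rnorm(100 * 4), 100, 4), Y = matrix(rnorm(100 * 2), 100, 2),
    segId = rep(1L, 100),
    folds = list(list(train = 1:80, val = 81:90, test = 91:100)),
    center = numeric(2), scale = numeric(2), M = 2L, p = 2L
  )
  net <- trainNetwork(td, fastConfig(p = 2, nReps = 1, maxEpochs = 2),
                      seed = 1)
  net@nets[[1]]$W1[] <- 0
  cn <- extractConnectivity(net, td)
  expect_equal(lC(cn), matrix(0, 2, 2), ignore_attr = TRUE)
  expect_equal(nC(cn), matrix(0, 2, 2), ignore_attr = TRUE)
})

test_that("linear coupling appears in lC and planted nonlinearity in NC", {
  ## VAR(1) with x1 -> x2 only: lC ranking must reflect it
  A <- array(0, c(2, 2, 1))
  A[2, 1, 1] <- 0.5; A[1, 1, 1] <- 0.3; A[2, 2, 1] <- 0.3
  x <- simulateNmvar(nmvarSpec(2, 1, A), 15000, seed = 1)
  td <- buildTrainingData(seriesContrast(x, 500), p = 1, seed = 1, nReps = 2)
  net <- trainNetwork(td, fastConfig(p = 1, maxEpochs = 40), seed = 1)
  cn <- extractConnectivity(net, td)
  expect_gt(lC(cn)[1, 2], lC(cn)[2, 1])
  ## planted quadratic coupling: NC_{1->2} significant, NC_{2->1} not
  sp <- nmvarSpec(2, 1, A = array(c(0.3, 0, 0, 0.3), c(2, 2, 1)),
                  nonlinearTerms = list(list(src = 1, lag = 1, tgt = 2,
                                             weight = 0.8, fun = "square")))
  xn <- simulateNmvar(sp, 8000, seed = 5)
  res <- surrogateTest(seriesContrast(xn, 400), fastConfig(p = 2), seed = 2)
  expect_lte(res@pNC[1, 2], 0.05)
  expect_gt(res@pNC[2, 1], 0.05)
  expect_gt(nC(res)[1, 2], res@surrogate$NCq95[1, 2])
  ## add-one rule: p-values never zero
  expect_true(all(res@pNC[!diag(2)] > 0))
  expect_true(all(res@pLC[!diag(2)] > 0))
})

test_that("circular shifting preserves each channel's power spectrum", {
  set.seed(8)
  x <- rnorm(512)
  k <- 137
  shifted <- c(x[(k + 1):512], x[1:k])
  expect_equal(Mod(fft(shifted)), Mod(fft(x)), tolerance = 1e-9)
})

test_that("subject selection enforces the eight-electrode rule", {
  set.seed(3)
  dat <- array(rnorm(8 * 7 * 120, sd = 1), c(8, 7, 120))
  ep <- makeEpochSet(dat, labels = gridLabels()[1:7],
                     gridXY = gridCoordinates()[1:7, ])
  expect_error(estimateConnectivity(ep, fastConfig()),
               class = "ncreann_subject_excluded")
  expect_error(estimateConnectivity(ep, fastConfig()),
               "insufficient channels")
})

test_that("a missing ninth electrode is interpolated before estimation", {
  set.seed(4)
  dat <- array(rnorm(10 * 9 * 150), c(10, 9, 150))
  ep <- makeEpochSet(dat)
  ep@badChannels <- "MC"
  cfg <- fastConfig(p = 2, maxTrials = 5, maxEpochs = 10,
                    surrogateMaxEpochs = 5, surrogateReps = 1)
  res <- estimateConnectivity(ep, cfg, seed = 1)
  expect_s4_class(res, "ConnectivityResult")
  expect_equal(dim(lC(res)), c(9, 9))
})

test_that("connectivity estimation is deterministic given the seed", {
  set.seed(5)
  dat <- array(rnorm(8 * 9 * 120), c(8, 9, 120))
  ep <- makeEpochSet(dat)
  cfg <- fastConfig(p = 2, maxEpochs = 8, surrogateMaxEpochs = 8,
                    surrogateReps = 1)
  r1 <- estimateConnectivity(ep, cfg, seed = 21)
  r2 <- estimateConnectivity(ep, cfg, seed = 21)
  expect_identical(lC(r1), lC(r2))
  expect_identical(nC(r1), nC(r2))
  expect_identical(r1@pNC, r2@pNC)
})

test_that("an end-to-end planted dependency tops the lC ranking", {
  ## 9-channel session-like series with one strong directed pair
  A <- array(0, c(9, 9, 1))
  diag(A[, , 1]) <- 0.3
  A[7, 2, 1] <- 0.6                      # channel 2 -> channel 7
  x <- simulateNmvar(nmvarSpec(9, 1, A), 18000, seed = 6)
  td <- buildTrainingData(seriesContrast(x, 500), p = 2, seed = 1, nReps = 2)
  attr(td, "channelLabels") <- gridLabels()
  net <- trainNetwork(td, fastConfig(p = 2, maxEpochs = 80, patience = 10), seed = 2)
  cn <- extractConnectivity(net, td)
  off <- lC(cn)
  diag(off) <- NA
  top <- which(off == max(off, na.rm = TRUE), arr.ind = TRUE)
  expect_equal(unname(top[1, ]), c(2, 7))
})
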