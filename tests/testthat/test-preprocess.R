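test_that("Kaiser design reproduces the protocol filter order and beta", {
  k <- designBandpassFir(3000, 0.1, 45, ripple = 0.001, transitionWidth = 0.2)
  expect_identical(k$order, 54330L)
  expect_equal(k$beta, 0.1102 * (60 - 8.7), tolerance = 1e-10)
  expect_equal(length(k$taps), 54331L)
  ## passband flat, DC and far stopband rejected
  expect_lt(abs(firGainDb(k, 20)), -20 * log10(1 - 0.001))
  expect_lt(firGainDb(k, 0), -60)
  expect_lt(firGainDb(k, 60), -60)
  expect_error(designBandpassFir(600, 50, 45), "band edges")
})

test_that("filtering preserves passband sinusoids and removes DC", {
  fs <- 600
  k <- designBandpassFir(fs, 0.1, 45, transitionWidth = 1)
  n <- 60000
  t <- (0:(n - 1)) / fs
  sig <- rbind(
    sin(2 * pi * 10 * t) + 100,       # passband + DC offset
    sin(2 * pi * 60 * t)              # stopband
  )
  rec <- new("EcogRecording",
    signal = sig, fs = fs, channelLabels = c("FC", "FL"),
    gridXY = gridCoordinates()[1:2, ], events = data.frame(),
    meta = list()
  )
  out <- signalMatrix(applyFilter(rec, k))
  core <- (k$order / 2 + 1):(n - k$order / 2)
  ## amplitude preserved within ripple, zero phase shift after compensation
  expect_equal(out[1, core], sin(2 * pi * 10 * t[core]), tolerance = 0.01)
  expect_lt(abs(mean(out[1, core])), 0.01)
  ## 60 Hz attenuated by >= 60 dB
  expect_lt(sd(out[2, core]), sd(sig[2, ]) * 10^(-60 / 20))
  expect_error(applyFilter(rec, designBandpassFir(500, 0.1, 45,
                                                  transitionWidth = 1)),
               "sampling rates")
})

test_that("epoching yields the documented window and baseline behaviour", {
  fs <- 3000
  n <- fs * 6
  sig <- matrix(5, 2, n)                       # constant 5 uV
  sig[2, ] <- 0
  onsets <- c(1, 2.5, 4)
  step <- round(onsets[2] * fs) + 1
  sig[2, step:n] <- 10                         # +10 uV step at second onset
  events <- data.frame(onset = onsets, tone_type = "standard",
                       tone_freq = 1000, level = 70, duration = 0.05,
                       block = 1)
  rec <- new("EcogRecording",
    signal = sig, fs = fs, channelLabels = c("FC", "FL"),
    gridXY = gridCoordinates()[1:2, ], events = events, meta = list()
  )
  ep <- epochAndBaseline(rec)
  expect_equal(dim(epochData(ep))[3], 2400)    # 0.8 s at 3 kHz, half-open
  expect_equal(range(timesMs(ep)), c(-100, 700 - 1000 / fs))
  ## constant channel is zero after baseline correction
  expect_equal(max(abs(epochData(ep)[, 1, ])), 0)
  ## step channel: pre-stimulus 0, post-stimulus 10 in the step trial
  pre <- timesMs(ep) < 0
  expect_equal(max(abs(epochData(ep)[2, 2, pre])), 0)
  expect_equal(unique(epochData(ep)[2, 2, !pre]), 10)
})

test_that("baseline correction is idempotent", {
  set.seed(1)
  dat <- array(rnorm(10 * 2 * 480), c(10, 2, 480))
  times <- seq(-100, by = 1000 / 600, length.out = 480)
  once <- ncreann:::baselineCorrect(dat, times)
  twice <- ncreann:::baselineCorrect(once, times)
  expect_equal(once, twice)
})

test_that("delta criterion rejects exactly the planted trials", {
  dat <- array(0, c(10, 3, 100))
  ep <- makeEpochSet(dat)
  r0 <- rejectArtifacts(ep, 500)
  expect_true(all(keptTrials(r0)))
  dat[7, 2, 50] <- 600
  dat[3, 1, 10] <- 499                          # just under threshold
  ep <- makeEpochSet(dat)
  r1 <- rejectArtifacts(ep, 500)
  expect_identical(which(!keptTrials(r1)), 7L)
  expect_identical(r1@meta$rejectionLog$trial, 7L)
  ## kept + rejected = extracted
  expect_equal(sum(keptTrials(r1)) + sum(!keptTrials(r1)), 10)
})

test_that("channels exceeding the rate threshold are marked bad", {
  dat <- array(0, c(10, 3, 100))
  dat[1:8, 2, 50] <- 700                        # channel 2 bad in 80% of trials
  ep <- makeEpochSet(dat)
  r <- rejectArtifacts(ep, 500)
  expect_identical(badChannels(r), gridLabels()[2])
  ## trials are judged on retained channels only
  expect_true(all(keptTrials(r)))
})

test_that("inverse-distance interpolation recovers planar fields", {
  xy <- gridCoordinates()
  nT <- 4; Tn <- 50
  ## identical signal everywhere
  s <- sin(seq_len(Tn) / 5)
  dat <- array(rep(s, each = nT * 9), c(nT, 9, Tn))
  ep <- makeEpochSet(dat, labels = gridLabels(), gridXY = xy)
  ip <- interpolateChannel(ep, "MC")
  expect_equal(ip@data[, 4, ], dat[, 4, ], tolerance = 1e-12)
  expect_identical(ip@interpolated, "MC")
  expect_equal(sum(ip@meta$interpolationWeights), 1)
  ## centre channel of a linear gradient field is recovered exactly
  grad <- 2 * xy[, 1] + 3 * xy[, 2]
  dat2 <- array(0, c(nT, 9, Tn))
  for (ch in 1:9) dat2[, ch, ] <- grad[ch]
  ep2 <- makeEpochSet(dat2, labels = gridLabels(), gridXY = xy)
  ip2 <- interpolateChannel(ep2, "MC")
  expect_equal(ip2@data[, 4, ], dat2[, 4, ], tolerance = 1e-12)
  ## too few good channels
  ep3 <- makeEpochSet(dat2[, 1:3, , drop = FALSE], labels = gridLabels()[1:3],
                      gridXY = xy[1:3, ])
  ep3@badChannels <- "FL"
  expect_error(interpolateChannel(ep3, "FC"), "at least 3")
})

test_that("filtering then epoching equals epoching a pre-filtered copy", {
  fs <- 600
  k <- designBandpassFir(fs, 0.1, 45, transitionWidth = 2)
  set.seed(7)
  n <- 20000
  sig <- matrix(rnorm(2 * n, sd = 10), 2, n)
  events <- data.frame(onset = c(5, 10, 15), tone_type = "standard",
                       tone_freq = 1000, level = 70, duration = 0.05,
                       block = 1)
  rec <- new("EcogRecording",
    signal = sig, fs = fs, channelLabels = c("FC", "FL"),
    gridXY = gridCoordinates()[1:2, ], events = events, meta = list()
  )
  e1 <- epochAndBaseline(applyFilter(rec, k))
  rec2 <- rec
  rec2@signal <- ncreann:::filterMatrix(sig, k$taps)
  e2 <- epochAndBaseline(rec2)
  expect_equal(epochData(e1), epochData(e2))
})

test_that("imputation is an identity on complete tables", {
  set.seed(1)
  x <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  out <- imputeFeatures(x)
  expect_equal(unclass(out), x, ignore_attr = TRUE)
  expect_identical(attr(out, "iterations"), 0L)
  xna <- x; xna[, 2] <- NA
  expect_error(imputeFeatures(xna), "all-missing")
})

test_that("imputation recovers strongly predictable cells", {
  nr <- list(twin = numeric(), lin = numeric(),
             twinBase = numeric(), linBase = numeric())
  for (s in 1:3) {
    set.seed(s)
    n <- 50
    x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
    x[, 5] <- x[, 4]
    mask <- sample(n, 10)
    xm <- x; xm[mask, 5] <- NA
    imp <- imputeFeatures(xm, seed = s + 10)
    nr$twin <- c(nr$twin, sqrt(mean((imp[mask, 5] - x[mask, 5])^2)) / sd(x[, 5]))
    nr$twinBase <- c(nr$twinBase,
      sqrt(mean((median(x[-mask, 5]) - x[mask, 5])^2)) / sd(x[, 5]))
    y <- cbind(x = rnorm(n), y = 0); y[, 2] <- 2 * y[, 1]
    ym <- y; m2 <- sample(n, 10); ym[m2, 2] <- NA
    imp2 <- imputeFeatures(ym, seed = s + 20)
    nr$lin <- c(nr$lin, sqrt(mean((imp2[m2, 2] - y[m2, 2])^2)) / sd(y[, 2]))
    nr$linBase <- c(nr$linBase,
      sqrt(mean((median(y[-m2, 2]) - y[m2, 2])^2)) / sd(y[, 2]))
  }
  ## normalised RMSE small in absolute terms and far below the
  ## median-fill baseline (tree ensembles cannot extrapolate, which
  ## floors the attainable NRMSE at the sample extremes)
  expect_lt(mean(nr$twin), 0.25)
  expect_lt(mean(nr$lin), 0.30)
  expect_lt(mean(nr$twin), 0.35 * mean(nr$twinBase))
  expect_lt(mean(nr$lin), 0.35 * mean(nr$linBase))
})

test_that("imputation is deterministic under a fixed seed", {
  set.seed(2)
  x <- matrix(rnorm(60), 15, 4, dimnames = list(NULL, paste0("f", 1:4)))
  x[c(2, 9), 3] <- NA
  expect_equal(imputeFeatures(x, seed = 5), imputeFeatures(x, seed = 5))
})
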