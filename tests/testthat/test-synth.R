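test_that("uncoupled nMVAR spec produces white noise", {
  x <- simulateNmvar(nmvarSpec(3, 1, noiseSd = 1), 5000, seed = 4)
  expect_equal(dim(x), c(3, 5000))
  for (i in 1:2) {
    cc <- cor(x[i, 1:4999], x[i + 1, 2:5000])
    expect_lt(abs(cc), 0.05)
  }
  expect_equal(apply(x, 1, sd), rep(1, 3), tolerance = 0.05)
})

test_that("least-squares refit recovers linear nMVAR coefficients", {
  A <- array(0, c(2, 2, 1))
  A[2, 1, 1] <- 0.5
  x <- simulateNmvar(nmvarSpec(2, 1, A), 10000, seed = 2)
  B <- qr.solve(cbind(1, t(x[, 1:9999])), t(x[, 2:10000]))
  expect_equal(B[2, 2], 0.5, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("quadratic nonlinear terms are generated as specified", {
  sp <- nmvarSpec(2, 1, nonlinearTerms = list(
    list(src = 1, lag = 1, tgt = 2, weight = 0.8, fun = "square")
  ))
  x <- simulateNmvar(sp, 10000, seed = 3)
  z <- x[1, 1:9999]^2
  co <- coef(lm(x[2, 2:10000] ~ z))
  expect_equal(unname(co[2]), 0.8, tolerance = 0.1)
})

test_that("unstable linear parts are rejected with the spectral radius", {
  A <- array(0, c(2, 2, 1))
  A[1, 1, 1] <- 1.2
  expect_error(nmvarSpec(2, 1, A), "spectral radius 1.2")
})

test_that("nMVAR simulation is reproducible under a fixed seed", {
  sp <- nmvarSpec(2, 2, ncreann:::randomStableVar(2, 2, 1))
  expect_identical(simulateNmvar(sp, 500, seed = 9),
                   simulateNmvar(sp, 500, seed = 9))
  expect_false(identical(simulateNmvar(sp, 500, seed = 9),
                         simulateNmvar(sp, 500, seed = 10)))
})

test_that("default oddball session exceeds 1600 events at a 13% share", {
  ev <- makeStimulusSequence(seed = 1)
  expect_gte(nrow(ev), 1600)
  nDev <- sum(ev$tone_type == "deviant")
  expect_lte(abs(nDev - 0.13 * nrow(ev)), 1)
  expect_true(all(diff(ev$onset) > 0))
  expect_equal(diff(ev$onset[1:2]), 1.05)
})

test_that("deviants are never adjacent and counts are exact over seeds", {
  for (s in 1:100) {
    ev <- makeStimulusSequence(nBlocks = 1, blockDuration = 60, seed = s)
    pos <- which(ev$tone_type == "deviant")
    expect_gt(min(diff(pos)), 1)
    expect_lte(abs(length(pos) - round(0.13 * nrow(ev))), 0)
  }
})

test_that("impossible deviant fractions raise an error", {
  expect_error(makeStimulusSequence(deviantFraction = 0.6), "0, 0.5")
})

test_that("noiseless injected component survives the whole ERP chain", {
  comp <- data.frame(name = "P1", latency_ms = 50, sigma_ms = 8,
                     amp_dev = 10, amp_std = 10)
  ev <- makeStimulusSequence(nBlocks = 1, blockDuration = 30, seed = 1)
  rec <- simulateSession(ev, fs = 600, seed = 1,
                         params = noiselessParams(comp))
  ep <- epochAndBaseline(rec)
  av <- averageAndDifference(ep)
  m <- av$deviant
  attr(m, "times") <- timesMs(ep)
  pk <- detectPeaks(m, windows = list(P1 = c(20, 80)))
  expect_equal(pk$latency_ms, rep(50, 9))
  expect_equal(pk$amplitude_uV, rep(10, 9), tolerance = 1e-6)
})

test_that("session generation is deterministic given events, preset, seed", {
  ev <- makeStimulusSequence(nBlocks = 1, blockDuration = 20, seed = 5)
  r1 <- simulateSession(ev, "alcohol_post", fs = 600, seed = 11)
  r2 <- simulateSession(ev, "alcohol_post", fs = 600, seed = 11)
  expect_identical(signalMatrix(r1), signalMatrix(r2))
  r3 <- simulateSession(ev, "alcohol_post", fs = 600, seed = 12)
  expect_false(identical(signalMatrix(r1), signalMatrix(r3)))
})

test_that("unknown presets are rejected with the valid list", {
  ev <- makeStimulusSequence(nBlocks = 1, blockDuration = 20, seed = 5)
  expect_error(simulateSession(ev, "sober_pre"), "control_pre")
})

test_that("planted artifacts are flagged exactly where injected", {
  ev <- makeStimulusSequence(nBlocks = 1, blockDuration = 120, seed = 2)
  bad <- c(5, 20, 60, 80, 100)
  rec <- simulateSession(ev, "control_pre", fs = 600, seed = 3,
                         artifactTrials = bad)
  ep <- rejectArtifacts(epochAndBaseline(rec), 500)
  rejected <- ep@meta$eventIndex[!keptTrials(ep)]
  expect_equal(rejected, bad)
})

test_that("alcohol preset reduces the group-mean P1N1 span", {
  p1n1 <- function(preset, seeds) {
    vapply(seeds, function(s) {
      ev <- makeStimulusSequence(nBlocks = 1, blockDuration = 120, seed = s)
      rec <- simulateSession(ev, preset, fs = 600, seed = s + 500)
      pk <- peakToPeak(detectPeaks(
        averageAndDifference(epochAndBaseline(rec))$difference
      ))
      mean(pk$amplitude_uV[pk$component == "P1N1"])
    }, numeric(1))
  }
  ctrl <- p1n1("control_pre", 1:5)
  alc <- p1n1("alcohol_pre", 6:10)
  expect_lt(mean(alc), mean(ctrl))
})

test_that("null ADE increment centres relapse at zero", {
  tab <- simulateDrinking(8, adeIncrement = c(0, 0, 0), seed = 1)
  dm <- drinkingMeasures(tab)
  tot <- dm$measures[is.na(dm$measures$concentration), ]
  expect_lt(abs(mean(tot$relapse)), 2 * sd(tot$relapse) / sqrt(nrow(tot)) + 0.1)
})

test_that("drinking generator recovers its configured cohort means", {
  tab <- simulateDrinking(10, seed = 42)
  dm <- drinkingMeasures(tab)
  tot <- dm$measures[is.na(dm$measures$concentration), ]
  sem <- function(v) sd(v) / sqrt(length(v))
  expect_lt(abs(mean(tot$bl) - 3.43), 2 * sem(tot$bl) + 0.1)
  expect_lt(abs(mean(tot$ade) - 4.66), 2 * sem(tot$ade) + 0.2)
  ## deprivation days have zero intake
  dep <- tab[grepl("^deprivation", tab$phase), ]
  expect_true(all(dep$intake == 0))
})

test_that("distinct seeds give distinct drinking tables, same structure", {
  t1 <- simulateDrinking(3, seed = 1)
  t2 <- simulateDrinking(3, seed = 2)
  expect_false(identical(t1$intake, t2$intake))
  expect_identical(t1[, c("rat", "day", "phase", "concentration")],
                   t2[, c("rat", "day", "phase", "concentration")])
})
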