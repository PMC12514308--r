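test_that("Mann-Whitney U and rank-biserial match brute-force enumeration", {
  bruteU <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  mw <- mannWhitneyEffect(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, bruteU(c(1, 2, 3), c(4, 5, 6)))   # 0
  expect_equal(mw$effectSize, 1)
  mw2 <- mannWhitneyEffect(c(1, 3), c(2, 4))
  expect_equal(mw2$U, bruteU(c(1, 3), c(2, 4)))        # 1
  mw3 <- mannWhitneyEffect(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw3$effectSize, 0)
  expect_equal(mw3$p, 1)
  set.seed(1)
  a <- rnorm(8); b <- rnorm(12)
  expect_equal(mannWhitneyEffect(a, b)$U, bruteU(a, b))
  expect_error(mannWhitneyEffect(numeric(), 1:3), "at least 2")
})

test_that("BH adjustment matches the hand-computed example and is monotone", {
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdrAdjust(0.2), 0.2)
  expect_equal(fdrAdjust(rep(0.07, 5)), rep(0.07, 5))
  set.seed(2)
  p <- runif(30)
  adj <- fdrAdjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  ## fixed points: fully tied adjusted vectors re-adjust to themselves
  expect_equal(fdrAdjust(fdrAdjust(c(0.01, 0.02, 0.03))),
               c(0.03, 0.03, 0.03))
  expect_error(fdrAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("mixed ANOVA agrees with hand-computed sums of squares", {
  ## 2 groups x 2 treatments x 3 channels, 3 subjects per group
  set.seed(7)
  d <- expand.grid(subject = sprintf("s%d", 1:6),
                   treatment = c("pre", "post"),
                   channel = c("FC", "ML", "PR"))
  d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= 3, "a", "b")
  d$value <- round(rnorm(nrow(d)), 1)
  an <- rmAnova(d)
  ## brute-force oracle: between-group F from subject means
  subjMean <- tapply(d$value, d$subject, mean)
  subjGroup <- tapply(d$group, d$subject, function(g) g[1])
  grand <- mean(subjMean)
  k <- 6                               # cells per subject
  ssG <- k * sum(tapply(subjMean, subjGroup, function(m) {
    length(m) * (mean(m) - grand)^2
  }))
  ssS <- k * sum((subjMean - ave(subjMean, subjGroup))^2)
  Fg <- (ssG / 1) / (ssS / 4)
  expect_equal(an$F[an$effect == "group"], Fg, tolerance = 1e-10)
  expect_equal(an$dfNum[an$effect == "group"], 1)
  expect_equal(an$dfDen[an$effect == "group"], 4)
  ## all effects present
  expect_setequal(an$effect, c(
    "group", "treatment", "channel", "group x treatment",
    "group x channel", "treatment x channel", "group x treatment x channel"
  ))
  expect_true(all(is.finite(an$pGG[grepl("channel", an$effect)])))
})

test_that("collapsed designs reduce to the paired t-test", {
  set.seed(3)
  tab <- data.frame(
    subject = rep(1:8, 2), group = "g",
    treatment = rep(c("pre", "post"), each = 8),
    channel = "FC", value = rnorm(16)
  )
  an <- rmAnova(tab)
  tt <- t.test(tab$value[9:16], tab$value[1:8], paired = TRUE)
  expect_equal(an$F[an$effect == "treatment"], unname(tt$statistic)^2,
               tolerance = 1e-10)
  ## all-equal data: no effect by convention
  tab$value <- 1
  an0 <- rmAnova(tab)
  expect_equal(an0$F, 0)
  expect_equal(an0$p, 1)
})

test_that("a pure group shift is detected and treatment stays null", {
  set.seed(11)
  hitsG <- 0
  pT <- numeric(20)
  for (r in 1:20) {
    d <- expand.grid(subject = sprintf("s%d", 1:10),
                     treatment = c("pre", "post"),
                     channel = c("FC", "ML"))
    d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= 5,
                      "control", "alcohol")
    d$value <- rnorm(nrow(d)) + ifelse(d$group == "alcohol", 2.5, 0)
    an <- rmAnova(d)
    if (an$p[an$effect == "group"] < 0.01) hitsG <- hitsG + 1
    pT[r] <- an$p[an$effect == "treatment"]
  }
  expect_gte(hitsG, 18)
  ## treatment p-values roughly uniform under the null
  expect_gt(mean(pT), 0.2)
  expect_lt(mean(pT), 0.8)
})

test_that("channelwise paired t handles identical and degenerate input", {
  set.seed(4)
  pre <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("FC", "ML", "PR")))
  same <- pairedTByChannel(pre, pre)
  expect_equal(same$t, rep(0, 3))
  expect_equal(same$p, rep(1, 3))
  shifted <- pairedTByChannel(pre, pre + 1)
  expect_true(all(shifted$zeroVariance))
  expect_true(all(shifted$p == 0))
  expect_true(all(is.infinite(shifted$t)))
  expect_error(pairedTByChannel(pre, pre[1:4, ]), "dimensions")
})

test_that("partial Spearman isolates and recovers partial association", {
  set.seed(5)
  n <- 200
  x <- rnorm(n); z <- rnorm(n)
  ps <- partialSpearman(x, x + 0.001 * rnorm(n), z)
  expect_gt(ps$rho, 0.99)
  ## y = covariate: partialling out removes the association
  rhos <- replicate(30, {
    z <- rnorm(50); x <- rnorm(50)
    partialSpearman(x, z + 0.001 * rnorm(50), z)$rho
  })
  expect_lt(abs(mean(rhos)), 0.1)
  ## trivariate normal with known partial correlation 0.5
  est <- replicate(20, {
    z <- rnorm(200)
    e1 <- rnorm(200); e2 <- 0.5 * e1 + sqrt(1 - 0.25) * rnorm(200)
    partialSpearman(z + e1, z + e2, z)$rho
  })
  expect_equal(mean(est), 0.5, tolerance = 0.1)
  expect_error(partialSpearman(rep(1, 10), rnorm(10), rnorm(10)), "constant")
})

test_that("drinking measures respect constants, additivity and the ADE", {
  ## constant intake: BL = ADE = c, relapse 0
  tab <- simulateDrinking(4, blMeans = c(`5` = 1, `10` = 1, `20` = 1),
                          adeIncrement = c(0, 0, 0), ratSd = 0, daySd = 0,
                          seed = 1)
  dm <- drinkingMeasures(tab)
  perc <- dm$measures[!is.na(dm$measures$concentration), ]
  expect_equal(perc$bl, rep(1, nrow(perc)))
  expect_equal(perc$ade, rep(1, nrow(perc)))
  expect_equal(perc$relapse, rep(0, nrow(perc)))
  ## totals are the sum over concentrations for every rat and measure
  tab2 <- simulateDrinking(6, seed = 3)
  dm2 <- drinkingMeasures(tab2)
  for (r in unique(dm2$measures$rat)) {
    m <- dm2$measures[dm2$measures$rat == r, ]
    tot <- m[is.na(m$concentration), ]
    pc <- m[!is.na(m$concentration), ]
    expect_equal(tot$bl, sum(pc$bl))
    expect_equal(tot$ade, sum(pc$ade))
    expect_equal(tot$relapse, sum(pc$relapse))
  }
  ## configured ADE increment is recovered and significant
  inc <- c(`5` = 0.5, `10` = 0.4, `20` = 0.4)
  tab3 <- simulateDrinking(10, adeIncrement = inc, seed = 5)
  dm3 <- drinkingMeasures(tab3)
  tot <- dm3$measures[is.na(dm3$measures$concentration), ]
  sem <- sd(tot$relapse) / sqrt(nrow(tot))
  expect_lt(abs(mean(tot$relapse) - 1.3), 2 * sem + 0.1)
  tt <- dm3$relapseTests
  expect_lt(tt$p[tt$concentration == "total"], 0.01)
  ## phase effect visible in the rmANOVA table
  expect_true("drinking_phase" %in% dm3$anova$effect)
  expect_error(drinkingMeasures(tab3[grepl("drinking_1", tab3$phase), ]),
               "deprivation")
})
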