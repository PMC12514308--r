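#' Single-trial contrast signals
#'
#' Subtracts the across-trials mean of the kept standard trials from every
#' kept deviant trial on the analysis window; the mean of the contrast
#' trials equals the deviant average minus the standard average.
#'
#' @param epochs an [EpochSet-class] with kept trials in both conditions.
#' @return a [ContrastSet-class].
#' @export
contrastTrials <- function(epochs) {
  stopifnot(is(epochs, "EpochSet"))
  devIdx <- which(epochs@condition == "deviant" & epochs@kept)
  stdIdx <- which(epochs@condition == "standard" & epochs@kept)
  stopIfNot(length(devIdx) > 0, "zero kept deviant trials")
  stopIfNot(length(stdIdx) > 0, "zero kept standard trials")
  stdMean <- apply(epochs@data[stdIdx, , , drop = FALSE], c(2, 3), mean)
  contr <- epochs@data[devIdx, , , drop = FALSE]
  contr <- sweep(contr, c(2, 3), stdMean, "-")
  new("ContrastSet",
    data = contr, times = epochs@times, fs = epochs@fs,
    channelLabels = epochs@channelLabels,
    meta = list(
      subject = epochs@meta$subject, treatment = epochs@meta$treatment,
      group = epochs@meta$group,
      nDeviant = length(devIdx), nStandard = length(stdIdx)
    )
  )
}

## Build a ContrastSet directly from a channels x samples matrix split
## into equal-length pseudo-trials; used for simulation studies.
contrastFromSeries <- function(x, trialLength = NULL, fs = 1000,
                               labels = NULL) {
  M <- nrow(x); n <- ncol(x)
  if (is.null(trialLength)) trialLength <- n
  nTr <- n %/% trialLength
  dat <- array(0, c(nTr, M, trialLength))
  for (t in seq_len(nTr)) {
    dat[t, , ] <- x[, ((t - 1) * trialLength + 1):(t * trialLength)]
  }
  new("ContrastSet",
    data = dat, times = (seq_len(trialLength) - 1) / fs * 1000, fs = fs,
    channelLabels = labels %||% sprintf("ch%d", seq_len(M)),
    meta = list()
  )
}

#' Lagged training rows and cross-validation splits for the nMVAR network
#'
#' Channels are z-scored with the statistics of the full concatenated
#' contrast series; lagged input rows are built strictly within trials
#' (the first `p` samples of a trial serve only as history, targets never
#' cross a trial boundary), with inputs ordered
#' `x1(n-1), ..., xM(n-1), x1(n-2), ..., xM(n-p)`. Ten (by default)
#' independently permuted 80/10/10 train/validation/test row splits are
#' attached.
#'
#' @param contrast a [ContrastSet-class].
#' @param p model order; must be smaller than the trial length.
#' @param seed integer seed for the permuted splits.
#' @param nReps number of permuted repetitions (default 10).
#' @param maxTrials optional cap on the number of contrast trials used
#'   (evenly subsampled), to bound training cost; default all.
#' @return a [TrainingData-class].
#' @export
buildTrainingData <- function(contrast, p = 8, seed = NULL, nReps = 10,
                              maxTrials = NULL) {
  stopifnot(is(contrast, "ContrastSet"))
  d <- dim(contrast@data)
  nTr <- d[1]; M <- d[2]; Tn <- d[3]
  stopIfNot(p >= 1 && p < Tn, "model order p must be below the trial length")
  useTr <- seq_len(nTr)
  if (!is.null(maxTrials) && maxTrials < nTr) {
    useTr <- unique(as.integer(round(seq(1, nTr, length.out = maxTrials))))
  }
  ## z-score per channel over the concatenated selected trials
  center <- numeric(M); scl <- numeric(M)
  for (ch in seq_len(M)) {
    v <- as.vector(contrast@data[useTr, ch, ])
    center[ch] <- mean(v)
    scl[ch] <- sd(v)
    if (scl[ch] == 0) scl[ch] <- 1
  }
  rowsPerTrial <- Tn - p
  N <- rowsPerTrial * length(useTr)
  X <- matrix(0, N, M * p)
  Y <- matrix(0, N, M)
  segId <- integer(N)
  at <- 0L
  for (t in useTr) {
    z <- (t(contrast@data[t, , ]) - matrix(center, Tn, M, byrow = TRUE)) /
      matrix(scl, Tn, M, byrow = TRUE)       # time x channels
    idx <- at + seq_len(rowsPerTrial)
    Y[idx, ] <- z[(p + 1):Tn, , drop = FALSE]
    for (k in seq_len(p)) {
      X[idx, (k - 1) * M + seq_len(M)] <- z[(p + 1 - k):(Tn - k), , drop = FALSE]
    }
    segId[idx] <- t
    at <- at + rowsPerTrial
  }
  folds <- withSeed(seed, {
    lapply(seq_len(nReps), function(r) {
      perm <- sample.int(N)
      nTrain <- floor(0.8 * N)
      nVal <- floor(0.1 * N)
      list(
        train = perm[seq_len(nTrain)],
        val = perm[nTrain + seq_len(nVal)],
        test = perm[(nTrain + nVal + 1):N]
      )
    })
  })
  new("TrainingData",
    X = X, Y = Y, segId = segId, folds = folds,
    center = center, scale = scl, M = as.integer(M), p = as.integer(p)
  )
}

#' Select the nMVAR model order by information criteria
#'
#' Fits linear MVAR models of order 1..`pMax` by least squares on
#' boundary-respecting lagged rows (a common target set from `pMax + 1`
#' onward so all candidates see identical data) and scores
#' `AIC(p) = ln det(Sigma_p) + 2 p M^2 / N` and
#' `BIC(p) = ln det(Sigma_p) + ln(N) p M^2 / N`, with `Sigma_p` the
#' residual covariance. The default pipeline order is fixed at 8; this
#' reports the criterion curves and their minimum.
#'
#' @param contrast a [ContrastSet-class].
#' @param pMax largest candidate order.
#' @param criterion `"bic"` (default) or `"aic"`.
#' @return an [OrderSelection-class].
#' @export
selectModelOrder <- function(contrast, pMax = 12, criterion = c("bic", "aic")) {
  stopifnot(is(contrast, "ContrastSet"))
  criterion <- match.arg(criterion)
  stopIfNot(pMax >= 1, "pMax must be >= 1")
  full <- buildTrainingData(contrast, p = pMax, seed = 1, nReps = 1)
  N <- nrow(full@X); M <- full@M
  tab <- data.frame(p = seq_len(pMax), aic = NA_real_, bic = NA_real_)
  for (p in seq_len(pMax)) {
    Xp <- cbind(1, full@X[, seq_len(M * p), drop = FALSE])
    fit <- lm.fit(Xp, full@Y)
    if (fit$rank < ncol(Xp)) {
      stop(sprintf(
        "singular design at order %d; try a lower pMax", p
      ), call. = FALSE)
    }
    res <- as.matrix(fit$residuals)
    Sig <- crossprod(res) / N
    ld <- determinant(Sig, logarithm = TRUE)
    stopIfNot(ld$sign > 0, "residual covariance is not positive definite")
    ldet <- as.numeric(ld$modulus)
    tab$aic[p] <- ldet + 2 * p * M^2 / N
    tab$bic[p] <- ldet + log(N) * p * M^2 / N
  }
  sc <- tab[[criterion]]
  new("OrderSelection",
    table = tab, chosen = as.integer(tab$p[which.min(sc)]),
    criterion = criterion
  )
}
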