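#' Training configuration for the connectivity estimator
#'
#' Defaults follow the reference analysis protocol: model order 8, 10
#' hidden units, momentum 0.9, initial learning rate 0.01, early-stopping
#' patience 6, 10 permuted cross-validation repetitions, 100 time-shifted
#' surrogates. The adaptive learning-rate rule grows eta by `etaUp` after
#' an epoch whose training MSE decreased and shrinks it by `etaDown`
#' (rolling the epoch back) when the MSE rose by more than `riseTol`.
#' `surrogateMaxEpochs`/`surrogateReps` allow a reduced training budget
#' for the surrogate reruns; `NULL` (the default) keeps the full budget.
#'
#' @param p model order (lags).
#' @param nHidden hidden units.
#' @param momentum momentum coefficient alpha.
#' @param eta0 initial learning rate.
#' @param maxEpochs maximum training epochs.
#' @param patience early-stopping patience in epochs.
#' @param nReps permuted cross-validation repetitions.
#' @param etaUp,etaDown,riseTol adaptive learning-rate constants.
#' @param initScale weight-initialisation scale (uniform bounds
#'   `initScale/sqrt(fan-in)`). Small values start the network in its
#'   near-linear regime, which keeps the nonlinear sensitivity (NC) of
#'   genuinely linear data at the surrogate level.
#' @param nSurrogates surrogate datasets for the randomisation test.
#' @param surrogateMaxEpochs,surrogateReps reduced surrogate budget
#'   (`NULL` = same as the main fit).
#' @param alpha significance level of the surrogate test.
#' @param maxTrials optional cap on contrast trials used (see
#'   [buildTrainingData()]).
#' @param rowSubsample cap on rows used for the connectivity ablation
#'   average (see [extractConnectivity()]).
#' @param minElectrodes subject-inclusion threshold (default 8).
#' @return named list of parameters.
#' @export
connectivityConfig <- function(p = 8, nHidden = 10, momentum = 0.9,
                               eta0 = 0.01, maxEpochs = 200, patience = 6,
                               nReps = 10, etaUp = 1.05, etaDown = 0.7,
                               riseTol = 0.04, initScale = 0.5,
                               nSurrogates = 100,
                               surrogateMaxEpochs = NULL,
                               surrogateReps = NULL, alpha = 0.05,
                               maxTrials = NULL, rowSubsample = 20000,
                               minElectrodes = 8) {
  stopIfNot(nHidden > 0 && eta0 > 0 && maxEpochs > 0 && patience > 0,
            "training parameters must be positive")
  list(
    p = p, nHidden = nHidden, momentum = momentum, eta0 = eta0,
    maxEpochs = maxEpochs, patience = patience, nReps = nReps,
    etaUp = etaUp, etaDown = etaDown, riseTol = riseTol,
    initScale = initScale, nSurrogates = nSurrogates,
    surrogateMaxEpochs = surrogateMaxEpochs, surrogateReps = surrogateReps,
    alpha = alpha, maxTrials = maxTrials, rowSubsample = rowSubsample,
    minElectrodes = minElectrodes
  )
}

#' Train the nMVAR perceptron over permuted cross-validation repetitions
#'
#' For each 80/10/10 repetition in the training data, fits the
#' one-hidden-layer network (tanh hidden, affine output) by incremental
#' back-propagation with momentum and adaptive learning rate, stopping
#' early on the validation split and restoring the best-validation
#' weights, then records train/test MSE and pooled R-squared. The
#' repetition with the median test MSE is flagged as the representative
#' network; all repetitions are retained for connectivity averaging.
#'
#' @param data a [TrainingData-class].
#' @param config a [connectivityConfig()] list.
#' @param seed integer seed (weight initialisation and presentation
#'   order).
#' @return a [TrainedNet-class].
#' @export
trainNetwork <- function(data, config = connectivityConfig(), seed = NULL) {
  stopifnot(is(data, "TrainingData"))
  stopIfNot(nrow(data@X) > 0, "training data is empty")
  nReps <- min(config$nReps, length(data@folds))
  seeds <- childSeeds(seed %||% 1L, nReps)
  nets <- vector("list", nReps)
  diag <- vector("list", nReps)
  for (r in seq_len(nReps)) {
    fold <- data@folds[[r]]
    fit <- cpp_train_mlp(
      data@X, data@Y, fold$train, fold$val,
      config$nHidden, config$momentum, config$eta0,
      config$maxEpochs, config$patience,
      config$etaUp, config$etaDown, config$riseTol,
      config$initScale %||% 0.5, as.integer(seeds[r])
    )
    if (isTRUE(fit$diverged)) {
      stop(sprintf(
        "training diverged (NaN loss) in repetition %d at epoch %d (eta %.3g)",
        r, fit$divergedEpoch, fit$finalEta
      ), call. = FALSE)
    }
    nets[[r]] <- fit[c("W1", "b1", "W2", "b2", "trainMse", "valMse",
                       "eta", "bestEpoch")]
    dTr <- netFitStats(fit, data@X, data@Y, fold$train)
    dTe <- netFitStats(fit, data@X, data@Y, fold$test)
    diag[[r]] <- data.frame(
      rep = r, mseTrain = dTr$mse, mseTest = dTe$mse,
      r2Train = dTr$r2, r2Test = dTe$r2,
      epochs = length(fit$trainMse), finalEta = fit$finalEta
    )
  }
  diag <- do.call(rbind, diag)
  ## representative fit: the repetition with median test MSE
  best <- order(diag$mseTest)[ceiling(nReps / 2)]
  new("TrainedNet",
    nets = nets, diagnostics = diag, best = as.integer(best),
    M = data@M, p = data@p, config = config
  )
}

## Forward pass of one fitted repetition.
netPredict <- function(net, X) {
  H <- tanh(X %*% t(net$W1) + matrix(net$b1, nrow(X), length(net$b1),
                                     byrow = TRUE))
  H %*% t(net$W2) + matrix(net$b2, nrow(X), length(net$b2), byrow = TRUE)
}

## MSE and pooled R^2 (1 - SSE/SST over all output channels) on a row set.
netFitStats <- function(net, X, Y, idx) {
  pred <- netPredict(net, X[idx, , drop = FALSE])
  truth <- Y[idx, , drop = FALSE]
  sse <- sum((pred - truth)^2)
  sst <- sum(sweep(truth, 2, colMeans(truth), "-")^2)
  list(mse = sse / length(truth), r2 = 1 - sse / sst)
}
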