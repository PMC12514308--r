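#' Fit the linear MVAR stage of the connectivity model
#'
#' Least-squares multivariate regression of the standardised targets on
#' the lagged inputs; the first stage of the linear/nonlinear
#' decomposition `f = f_lin + f_nonlin`. The network stage is trained on
#' the residuals of this fit, so that on purely linear systems the
#' network faces the same structureless input as the time-shifted
#' surrogates and the nonlinear connectivity stays at its null level.
#'
#' @param data a [TrainingData-class].
#' @return list: `B` (M x M*p coefficient matrix, target x lagged input),
#'   `intercept` (length M), `residuals` (rows x M).
#' @export
linearStageFit <- function(data) {
  stopifnot(is(data, "TrainingData"))
  fit <- lm.fit(cbind(1, data@X), data@Y)
  cf <- as.matrix(fit$coefficients)
  ## exactly collinear inputs (e.g. an interpolated channel) alias some
  ## coefficients; the pivoted fit leaves them NA with valid residuals
  cf[is.na(cf)] <- 0
  list(B = t(cf[-1, , drop = FALSE]), intercept = cf[1, ],
       residuals = as.matrix(fit$residuals))
}

#' Extract linear and nonlinear directed connectivity
#'
#' Decomposes the fitted model `f = f_lin + f_nonlin`. The linear part
#' combines the least-squares MVAR stage (when supplied) with the
#' network's data-averaged Jacobian (the least-squares linear component
#' of the learned function for standardised near-Gaussian inputs):
#' `lC[i -> j]` is the sum over lags of the absolute linear coefficients
#' mapping lagged channel i into target j. The nonlinear part is
#' measured by ablation on the network's nonlinear remainder:
#' `NC[i -> j]` is the mean absolute change of
#' `f_nonlin_j = net_j(u) - Jbar_j u` when channel i's lagged inputs are
#' set to their (zero) mean. Both are averaged across the
#' cross-validation repetitions. Matrices are oriented from-row
#' to-column; self-connections are computed but excluded from testing
#' and group reporting.
#'
#' @param net a [TrainedNet-class] (trained on the residuals of
#'   `linear` when a linear stage is used).
#' @param data the [TrainingData-class] the network was trained on.
#' @param linear optional [linearStageFit()] result; its coefficients
#'   are added to the network's linear part.
#' @param rowSubsample cap on rows used for the ablation average
#'   (evenly subsampled; default 20000).
#' @return a [ConnectivityResult-class] without surrogate significance.
#' @export
extractConnectivity <- function(net, data, linear = NULL,
                                rowSubsample = 20000) {
  stopifnot(is(net, "TrainedNet"), is(data, "TrainingData"))
  M <- net@M; p <- net@p
  stopIfNot(ncol(data@X) == M * p, "network and data dimensions differ")
  lCacc <- matrix(0, M, M)
  NCacc <- matrix(0, M, M)
  Blin <- if (is.null(linear)) matrix(0, M, M * p) else linear$B
  for (r in seq_along(net@nets)) {
    w <- net@nets[[r]]
    rows <- data@folds[[r]]$train
    if (length(rows) > rowSubsample) {
      rows <- rows[unique(as.integer(round(
        seq(1, length(rows), length.out = rowSubsample)
      )))]
    }
    X <- data@X[rows, , drop = FALSE]
    fwd <- function(Xi) {
      H <- tanh(Xi %*% t(w$W1) +
                  matrix(w$b1, nrow(Xi), length(w$b1), byrow = TRUE))
      H %*% t(w$W2) + matrix(w$b2, nrow(Xi), length(w$b2), byrow = TRUE)
    }
    Z <- X %*% t(w$W1) + matrix(w$b1, nrow(X), length(w$b1), byrow = TRUE)
    dBar <- colMeans(1 - tanh(Z)^2)
    ## data-averaged Jacobian: the linear component of the learned net
    Jbar <- w$W2 %*% (w$W1 * dBar)          # M x (M*p)
    Btot <- Blin + Jbar
    Fu <- fwd(X)
    for (j in seq_len(M)) {
      lCacc[, j] <- lCacc[, j] + rowSums(abs(matrix(Btot[j, ], M, p)))
    }
    for (i in seq_len(M)) {
      cols <- (seq_len(p) - 1) * M + i
      Xa <- X
      Xa[, cols] <- 0
      dNL <- (Fu - fwd(Xa)) -
        X[, cols, drop = FALSE] %*% t(Jbar[, cols, drop = FALSE])
      NCacc[i, ] <- NCacc[i, ] + colMeans(abs(dNL))
    }
  }
  nR <- length(net@nets)
  lCm <- lCacc / nR
  NCm <- NCacc / nR
  labels <- attr(data, "channelLabels") %||% sprintf("ch%d", seq_len(M))
  dimnames(lCm) <- dimnames(NCm) <- list(from = labels, to = labels)
  empty <- matrix(NA_real_, M, M)
  new("ConnectivityResult",
    lC = lCm, NC = NCm, channelLabels = labels,
    surrogate = list(), pLC = empty, pNC = empty,
    sigLC = matrix(FALSE, M, M), sigNC = matrix(FALSE, M, M),
    alpha = NA_real_,
    meta = list(diagnostics = net@diagnostics, p = p)
  )
}

## Two-stage estimate from prepared training rows: least-squares linear
## stage, network trained on the residuals, lC/NC extraction.
fitFromData <- function(data, config, seedTrain) {
  lin <- linearStageFit(data)
  dataR <- data
  dataR@Y <- lin$residuals
  net <- trainNetwork(dataR, config, seed = seedTrain)
  extractConnectivity(net, dataR, linear = lin,
                      rowSubsample = config$rowSubsample %||% 20000)
}

## Full two-stage estimate on one ContrastSet.
fitConnectivity <- function(contrast, config, seedBuild, seedTrain,
                            nReps = NULL) {
  cfg <- config
  if (!is.null(nReps)) cfg$nReps <- nReps
  data <- buildTrainingData(contrast, cfg$p, seed = seedBuild,
                            nReps = cfg$nReps)
  attr(data, "channelLabels") <- contrast@channelLabels
  fitFromData(data, cfg, seedTrain)
}

#' Time-shifted surrogate significance test for connectivity
#'
#' Randomisation test built on time-shifted surrogates: a surrogate
#' circularly shifts a channel's concatenated contrast series by a random
#' offset uniform in `[0.1 L, 0.9 L]`, which preserves that channel's
#' spectrum and dynamics while destroying its causal alignment with the
#' other channels. The null for the connections out of source channel i
#' shifts channel i's predictor (lagged-input) copy only, leaving all
#' targets and the other channels' predictors aligned, and reruns the
#' full estimate (linear stage, training, extraction) with the same
#' configuration (optionally a reduced epoch budget). This is the
#' conditional-independence null "past of channel i is unrelated to the
#' present given the other channels": every feature of the data not
#' involving channel i's outgoing influence - including genuine
#' nonlinear structure elsewhere, whose learned curvature spills weakly
#' into all connections of a shared-hidden-layer network - is present
#' under the null as well. Per connection the add-one permutation
#' p-value is `(1 + #{surrogate >= observed}) / (1 + nSurrogates)`; the
#' significance mask is thresholded at `config$alpha` with
#' self-connections excluded.
#'
#' @param contrast a [ContrastSet-class].
#' @param config a [connectivityConfig()].
#' @param seed integer seed.
#' @param observed optional precomputed observed
#'   [ConnectivityResult-class]; computed with the main budget when
#'   missing.
#' @return a [ConnectivityResult-class] with surrogate null summary,
#'   p-values and masks.
#' @export
surrogateTest <- function(contrast, config = connectivityConfig(),
                          seed = NULL, observed = NULL) {
  stopifnot(is(contrast, "ContrastSet"))
  nS <- config$nSurrogates
  stopIfNot(nS >= 20, "at least 20 surrogates are required")
  d <- dim(contrast@data)
  nTr <- d[1]; M <- d[2]; Tn <- d[3]
  L <- nTr * Tn
  seeds <- childSeeds(seed %||% 1L, 2L * nS * M + 2L)
  if (is.null(observed)) {
    observed <- fitConnectivity(contrast, config,
                                seedBuild = seeds[2L * nS * M + 1L],
                                seedTrain = seeds[2L * nS * M + 2L])
  }
  surCfg <- config
  if (!is.null(config$surrogateMaxEpochs)) {
    surCfg$maxEpochs <- config$surrogateMaxEpochs
  }
  surCfg$nReps <- config$surrogateReps %||% config$nReps
  ## concatenated channels x (trials * time) series, trial-major
  concat <- matrix(0, M, L)
  for (t in seq_len(nTr)) {
    concat[, ((t - 1) * Tn + 1):(t * Tn)] <- contrast@data[t, , ]
  }
  base <- buildTrainingData(contrast, config$p, seed = seeds[1L],
                            nReps = surCfg$nReps)
  attr(base, "channelLabels") <- contrast@channelLabels
  p <- config$p
  ## concatenated-series position feeding each lag column, in row order
  rowsPerTrial <- Tn - p
  posIdx <- lapply(seq_len(p), function(k) {
    unlist(lapply(seq_len(nTr), function(t) {
      (t - 1) * Tn + (p + 1 - k):(Tn - k)
    }))
  })
  lCs <- array(NA_real_, c(nS, M, M))
  NCs <- array(NA_real_, c(nS, M, M))
  lCn <- array(NA_real_, c(nS, M, M))
  NCn <- array(NA_real_, c(nS, M, M))
  for (s in seq_len(nS)) {
    for (i in seq_len(M)) {
      sd1 <- seeds[(s - 1L) * M + i]
      sd2 <- seeds[nS * M + (s - 1L) * M + i]
      ## shift channel i's predictor copy; targets stay aligned
      zi <- withSeed(sd1, {
        k <- floor(runif(1, 0.1 * L, 0.9 * L)) %% L
        v <- if (k > 0) c(concat[i, (k + 1):L], concat[i, 1:k]) else concat[i, ]
        (v - base@center[i]) / base@scale[i]
      })
      Xs <- base@X
      for (k in seq_len(p)) {
        Xs[, (k - 1) * M + i] <- zi[posIdx[[k]]]
      }
      dataS <- base
      dataS@X <- Xs
      sres <- fitFromData(dataS, surCfg, seedTrain = sd2)
      ## only the shifted source's outgoing row is a valid null draw;
      ## the same fit's remaining rows provide its studentising level
      lCs[s, i, ] <- sres@lC[i, ]
      NCs[s, i, ] <- sres@NC[i, ]
      lCn[s, i, ] <- sres@lC[i, ] / rowLevel(sres@lC, i)
      NCn[s, i, ] <- sres@NC[i, ] / rowLevel(sres@NC, i)
    }
  }
  pOf <- function(obs, surNorm) {
    pm <- matrix(NA_real_, M, M)
    for (i in seq_len(M)) {
      lev <- rowLevel(obs, i)
      for (j in seq_len(M)) {
        if (i == j) next
        pm[i, j] <- (1 + sum(surNorm[, i, j] >= obs[i, j] / lev)) / (1 + nS)
      }
    }
    pm
  }
  pLC <- pOf(observed@lC, lCn)
  pNC <- pOf(observed@NC, NCn)
  q95 <- function(a) apply(a, c(2, 3), quantile, probs = 0.95)
  observed@surrogate <- list(
    nSurrogates = nS,
    lCmean = apply(lCs, c(2, 3), mean), lCq95 = q95(lCs),
    NCmean = apply(NCs, c(2, 3), mean), NCq95 = q95(NCs)
  )
  observed@pLC <- pLC
  observed@pNC <- pNC
  observed@sigLC <- !is.na(pLC) & pLC <= config$alpha
  observed@sigNC <- !is.na(pNC) & pNC <= config$alpha
  observed@alpha <- config$alpha
  validObject(observed)
  observed
}

#' Estimate directed connectivity for one subject
#'
#' Orchestrates the full estimator on an epoched session: subject
#' selection (at least `minElectrodes` usable electrodes, a missing ninth
#' channel interpolated by inverse-distance weighting), single-trial
#' contrast construction, optional band-restriction and trial
#' subsampling, lagged training-data assembly at the configured order,
#' network training over permuted repetitions, Jacobian-based lC/NC
#' extraction, and the time-shifted surrogate significance test.
#'
#' @param epochs an [EpochSet-class] (after artifact rejection).
#' @param config a [connectivityConfig()].
#' @param seed integer seed.
#' @param band optional band restriction: `"broadband"` (none) or one of
#'   `"low_beta"`, `"mid_beta"`, `"high_beta"` (the contrast series is
#'   band-pass filtered before estimation), or a numeric `c(lo, hi)` Hz.
#' @return a [ConnectivityResult-class]. Subjects with fewer usable
#'   electrodes raise a condition of class `ncreann_subject_excluded`.
#' @export
estimateConnectivity <- function(epochs, config = connectivityConfig(),
                                 seed = NULL, band = "broadband") {
  stopifnot(is(epochs, "EpochSet"))
  usable <- setdiff(epochs@channelLabels, epochs@badChannels)
  if (length(usable) < config$minElectrodes) {
    stop(structure(
      class = c("ncreann_subject_excluded", "error", "condition"),
      list(message = sprintf(
        "insufficient channels: %d usable, %d required (subject %s)",
        length(usable), config$minElectrodes,
        epochs@meta$subject %||% "?"
      ), call = NULL)
    ))
  }
  for (bc in epochs@badChannels) {
    epochs <- interpolateChannel(epochs, bc)
  }
  contrast <- contrastTrials(epochs)
  if (!is.null(config$maxTrials) && dim(contrast@data)[1] > config$maxTrials) {
    sel <- unique(as.integer(round(
      seq(1, dim(contrast@data)[1], length.out = config$maxTrials)
    )))
    contrast@data <- contrast@data[sel, , , drop = FALSE]
  }
  if (!identical(band, "broadband")) {
    contrast <- bandRestrictContrast(contrast, band)
  }
  seeds <- childSeeds(seed %||% 1L, 3L)
  observed <- fitConnectivity(contrast, config, seedBuild = seeds[1],
                              seedTrain = seeds[2])
  res <- surrogateTest(contrast, config, seed = seeds[3], observed = observed)
  res@meta$subject <- epochs@meta$subject
  res@meta$group <- epochs@meta$group
  res@meta$treatment <- epochs@meta$treatment
  res@meta$band <- band
  res
}

## Studentising level of a connectivity matrix for source row i: the mean
## off-diagonal value over all OTHER rows (unaffected by shifting source
## i), which carries the estimate's global fit-noise/curvature level.
rowLevel <- function(m, i) {
  off <- !diag(nrow(m))
  off[i, ] <- FALSE
  max(mean(m[off]), .Machine$double.eps)
}

## Band-pass the concatenated contrast series per channel, then re-split
## into trials. Used for the beta-subrange connectivity variants.
bandRestrictContrast <- function(contrast, band, transitionWidth = 2) {
  if (is.character(band)) {
    bd <- erspBands()[[band]]
    stopIfNot(!is.null(bd), sprintf("unknown band '%s'", band))
  } else {
    bd <- band
  }
  d <- dim(contrast@data)
  nTr <- d[1]; M <- d[2]; Tn <- d[3]
  concat <- matrix(0, M, nTr * Tn)
  for (t in seq_len(nTr)) {
    concat[, ((t - 1) * Tn + 1):(t * Tn)] <- contrast@data[t, , ]
  }
  kern <- designBandpassFir(contrast@fs, bd[1], bd[2],
                            transitionWidth = transitionWidth)
  stopIfNot(ncol(concat) >= length(kern$taps),
            "contrast series shorter than the band-restriction filter")
  filt <- filterMatrix(concat, kern$taps)
  out <- contrastFromSeries(filt, Tn, contrast@fs, contrast@channelLabels)
  out@times <- contrast@times
  out@meta <- c(contrast@meta, list(band = bd))
  out
}
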