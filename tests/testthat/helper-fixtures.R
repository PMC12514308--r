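## Shared fixture builders: everything is generated in code at test time.

## Minimal EpochSet straight from a trials x channels x time array.
makeEpochSet <- function(dat, fs = 600, condition = NULL, times = NULL,
                         labels = NULL, gridXY = NULL) {
  d <- dim(dat)
  if (is.null(times)) times <- seq(-100, by = 1000 / fs, length.out = d[3])
  if (is.null(condition)) {
    condition <- rep(c("standard", "deviant"), length.out = d[1])
  }
  if (is.null(labels)) labels <- gridLabels()[seq_len(d[2])]
  if (is.null(gridXY)) {
    gridXY <- gridCoordinates()[seq_len(d[2]), , drop = FALSE]
  }
  new("EpochSet",
    data = dat, times = times,
    condition = factor(condition, levels = c("standard", "deviant")),
    kept = rep(TRUE, d[1]), fs = fs, channelLabels = labels,
    badChannels = character(), interpolated = character(),
    gridXY = gridXY, meta = list(subject = "t01")
  )
}

## Epochs with a known post-stimulus oscillatory burst over a small noise
## floor, identical on every trial (up to the floor).
makeBurstEpochs <- function(ampDev, ampStd = 0, freq = 10, center = 300,
                            sigma = 60, fs = 600, nTrials = 30,
                            noiseSd = 0.05, seed = 1) {
  times <- seq(-100, 700 - 1000 / fs, by = 1000 / fs)
  Tn <- length(times)
  set.seed(seed)
  dat <- array(rnorm(nTrials * 2 * Tn, sd = noiseSd), c(nTrials, 2, Tn))
  cond <- rep(c("standard", "deviant"), length.out = nTrials)
  env <- exp(-(times - center)^2 / (2 * sigma^2))
  carrier <- sin(2 * pi * freq * (times - center) / 1000)
  for (t in seq_len(nTrials)) {
    amp <- if (cond[t] == "deviant") ampDev else ampStd
    for (ch in 1:2) dat[t, ch, ] <- dat[t, ch, ] + amp * env * carrier
  }
  makeEpochSet(dat, fs = fs, condition = cond, times = times,
               labels = c("A", "B"), gridXY = matrix(0, 2, 2))
}

## Noise-free session parameters with custom evoked components.
noiselessParams <- function(components, bursts = NULL) {
  p <- sessionPresets("control_pre")
  p$components <- components
  p$bursts <- if (is.null(bursts)) p$bursts[0, ] else bursts
  p$backgroundSd <- 0
  p$sensorNoiseSd <- 0
  p$trialJitterSd <- 0
  p$channelGain <- setNames(rep(1, 9), gridLabels())
  p
}

## ContrastSet from a channels x samples matrix cut into pseudo-trials.
seriesContrast <- function(x, trialLength, fs = 1000) {
  ncreann:::contrastFromSeries(x, trialLength, fs)
}

## Fast training configuration for unit-scale connectivity runs.
fastConfig <- function(...) {
  ## small eta0: the SGD fluctuation floor at the pipeline default (0.01)
  ## masks weak linear signal in the desk-scale simulation studies
  args <- list(
    nReps = 2, maxEpochs = 60, patience = 8, eta0 = 0.003, nSurrogates = 20,
    surrogateMaxEpochs = 60, surrogateReps = 2
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(connectivityConfig, args)
}

## Magnitude response of an FIR kernel at one frequency.
firGainDb <- function(kernel, f) {
  n <- length(kernel$taps)
  20 * log10(abs(sum(kernel$taps * exp(-2i * pi * f * (0:(n - 1)) / kernel$fs))))
}
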