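#' Continuous multichannel ECoG recording
#'
#' Holds a channels x samples signal matrix in microvolts together with the
#' sampling rate, channel labels and planar grid coordinates, the stimulus
#' event table, and free-form subject metadata (subject id, group,
#' treatment).
#'
#' @slot signal numeric matrix, channels x samples (microvolts).
#' @slot fs sampling rate in Hz.
#' @slot channelLabels character vector, one label per signal row.
#' @slot gridXY numeric matrix (channels x 2) of planar electrode
#'   coordinates in mm.
#' @slot events data.frame event table (columns `onset`, `tone_type`,
#'   `tone_freq`, `level`, `duration`, `block`).
#' @slot meta named list of subject metadata.
#' @export
setClass("EcogRecording", representation(
  signal = "matrix",
  fs = "numeric",
  channelLabels = "character",
  gridXY = "matrix",
  events = "data.frame",
  meta = "list"
))

setValidity("EcogRecording", function(object) {
  msg <- character()
  if (length(object@channelLabels) != nrow(object@signal)) {
    msg <- c(msg, "length(channelLabels) must equal nrow(signal)")
  }
  if (length(object@fs) != 1L || object@fs <= 0) {
    msg <- c(msg, "fs must be a single positive number")
  }
  if (length(object@fs) == 1L && object@fs <= 2 * 45) {
    msg <- c(msg, "fs must exceed twice the highest analysis frequency (45 Hz)")
  }
  if (nrow(object@events) > 0) {
    dur <- ncol(object@signal) / object@fs
    if (any(object@events$onset >= dur)) {
      msg <- c(msg, "all event onsets must fall inside the recording")
    }
  }
  if (nrow(object@gridXY) != nrow(object@signal)) {
    msg <- c(msg, "gridXY must have one row per channel")
  }
  if (length(msg)) msg else TRUE
})

#' Epoched trials around stimulus onsets
#'
#' Trials x channels x time array cut around stimulus onsets, with the time
#' axis in ms relative to onset, a condition label per trial, and a
#' kept-mask tracking artifact rejection.
#'
#' @slot data numeric array, trials x channels x time (microvolts).
#' @slot times numeric vector of sample times in ms relative to onset.
#' @slot condition factor per trial, levels `standard`/`deviant`.
#' @slot kept logical per trial; `FALSE` after artifact rejection.
#' @slot fs sampling rate in Hz.
#' @slot channelLabels character vector.
#' @slot badChannels character vector of channels marked unusable.
#' @slot interpolated character vector of channels replaced by
#'   interpolation.
#' @slot gridXY planar electrode coordinates (channels x 2, mm).
#' @slot meta named list (subject metadata, rejection log, dropped trials).
#' @export
setClass("EpochSet", representation(
  data = "array",
  times = "numeric",
  condition = "factor",
  kept = "logical",
  fs = "numeric",
  channelLabels = "character",
  badChannels = "character",
  interpolated = "character",
  gridXY = "matrix",
  meta = "list"
))

setValidity("EpochSet", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 3L) msg <- c(msg, "data must be a 3-d array")
  if (length(object@times) != d[3]) msg <- c(msg, "times must match dim 3")
  if (length(object@condition) != d[1]) msg <- c(msg, "condition must match dim 1")
  if (length(object@kept) != d[1]) msg <- c(msg, "kept must match dim 1")
  if (length(object@channelLabels) != d[2]) msg <- c(msg, "channelLabels must match dim 2")
  if (length(msg)) msg else TRUE
})

#' Deviant-minus-standard difference ERP
#'
#' Channels x time matrix of the deviant-average minus standard-average
#' event-related potential, with provenance.
#'
#' @slot data channels x time matrix (microvolts).
#' @slot times ms relative to onset.
#' @slot channelLabels character vector.
#' @slot fs Hz.
#' @slot provenance list (subject, treatment, trials per condition).
#' @export
setClass("DifferenceErp", representation(
  data = "matrix",
  times = "numeric",
  channelLabels = "character",
  fs = "numeric",
  provenance = "list"
))

#' Event-related spectral perturbation map
#'
#' Channels x frequencies x times array of baseline-normalised power in dB
#' (10*log10 of the post/pre power ratio), cropped to 1-45 Hz.
#'
#' @slot power array channels x freqs x times (dB).
#' @slot freqs Hz.
#' @slot times ms (window centres).
#' @slot channelLabels character.
#' @slot params list of analysis parameters (window, pad ratio, taper).
#' @export
setClass("ErspMap", representation(
  power = "array",
  freqs = "numeric",
  times = "numeric",
  channelLabels = "character",
  params = "list"
))

setValidity("ErspMap", function(object) {
  msg <- character()
  if (any(!is.finite(object@power))) msg <- c(msg, "power must be finite")
  if (any(object@freqs < 1 - 1e-9) || any(object@freqs > 45 + 1e-9)) {
    msg <- c(msg, "frequency axis must lie within [1, 45] Hz")
  }
  if (length(msg)) msg else TRUE
})

#' Single-trial contrast signals for connectivity estimation
#'
#' Each kept deviant trial minus the mean of kept standard trials, on the
#' analysis window; the input to nMVAR network training.
#'
#' @slot data array, contrast trials x channels x time (microvolts).
#' @slot times ms relative to onset.
#' @slot fs Hz.
#' @slot channelLabels character.
#' @slot meta list.
#' @export
setClass("ContrastSet", representation(
  data = "array",
  times = "numeric",
  fs = "numeric",
  channelLabels = "character",
  meta = "list"
))

#' Lagged training rows for the nMVAR network
#'
#' Standardised lagged input rows (M*p columns ordered x1(n-1)..xM(n-1),
#' x1(n-2)..xM(n-p)) and M-column targets, built within trials only, with
#' the 10 permuted 80/10/10 train/validation/test splits.
#'
#' @slot X input matrix, rows x (M*p).
#' @slot Y target matrix, rows x M.
#' @slot segId integer trial id per row.
#' @slot folds list of repetitions, each a list(train, val, test) of row
#'   indices.
#' @slot center,scale per-channel standardisation constants.
#' @slot M,p channel count and model order.
#' @export
setClass("TrainingData", representation(
  X = "matrix",
  Y = "matrix",
  segId = "integer",
  folds = "list",
  center = "numeric",
  scale = "numeric",
  M = "integer",
  p = "integer"
))

#' Trained nMVAR perceptron (all cross-validation repetitions)
#'
#' One-hidden-layer (10 tanh units, affine output) networks trained by
#' incremental back-propagation with momentum and adaptive learning rate;
#' one weight set per permuted repetition plus per-repetition diagnostics.
#'
#' @slot nets list per repetition: W1, b1, W2, b2, trace, bestEpoch.
#' @slot diagnostics data.frame: rep, mseTrain, mseTest, r2Train, r2Test,
#'   epochs, finalEta.
#' @slot best integer index of the repetition with median test MSE.
#' @slot M,p dimensions.
#' @slot config list of training parameters.
#' @export
setClass("TrainedNet", representation(
  nets = "list",
  diagnostics = "data.frame",
  best = "integer",
  M = "integer",
  p = "integer",
  config = "list"
))

setValidity("TrainedNet", function(object) {
  if (object@best < 1L || object@best > length(object@nets)) {
    return("best must index into nets")
  }
  TRUE
})

#' Directed linear and nonlinear connectivity matrices
#'
#' lC and NC matrices oriented from-row to-column, optionally with the
#' time-shifted surrogate null (per-connection mean and 95th percentile),
#' permutation p-values and the significance mask at level alpha.
#' Self-connections are excluded from testing and reporting.
#'
#' @slot lC,NC numeric M x M matrices (non-negative sensitivity units).
#' @slot channelLabels character.
#' @slot surrogate list or empty: nSurrogates, lCmean, lCq95, NCmean, NCq95.
#' @slot pLC,pNC p-value matrices (NA where untested).
#' @slot sigLC,sigNC logical masks at alpha.
#' @slot alpha significance level.
#' @slot meta list (diagnostics, config echo).
#' @export
setClass("ConnectivityResult", representation(
  lC = "matrix",
  NC = "matrix",
  channelLabels = "character",
  surrogate = "list",
  pLC = "matrix",
  pNC = "matrix",
  sigLC = "matrix",
  sigNC = "matrix",
  alpha = "numeric",
  meta = "list"
))

setValidity("ConnectivityResult", function(object) {
  msg <- character()
  if (any(object@lC < 0) || any(object@NC < 0)) {
    msg <- c(msg, "lC and NC must be non-negative")
  }
  pv <- c(object@pLC, object@pNC)
  pv <- pv[!is.na(pv)]
  if (length(pv) && (any(pv <= 0) || any(pv > 1))) {
    msg <- c(msg, "p-values must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' nMVAR model-order selection by information criteria
#'
#' AIC and BIC curves of a linear MVAR fit by least squares over candidate
#' orders, and the order minimising the configured criterion.
#'
#' @slot table data.frame: p, aic, bic.
#' @slot chosen integer chosen order.
#' @slot criterion "aic" or "bic".
#' @export
setClass("OrderSelection", representation(
  table = "data.frame",
  chosen = "integer",
  criterion = "character"
))

setValidity("OrderSelection", function(object) {
  sc <- object@table[[object@criterion]]
  if (object@table$p[which.min(sc)] != object@chosen) {
    return("chosen order must minimise the configured criterion")
  }
  TRUE
})
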