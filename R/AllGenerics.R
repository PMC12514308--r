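#' Accessors for ncreann data classes
#'
#' Small accessor generics: sampling rate, channel labels, time axis,
#' event table, signal/epoch data, kept-trial mask, condition labels, and
#' the connectivity matrices.
#'
#' @param object an ncreann S4 object.
#' @name accessors
#' @aliases samplingRate,EcogRecording-method samplingRate,EpochSet-method
#'   samplingRate,ContrastSet-method samplingRate,DifferenceErp-method
#'   channelLabels,EcogRecording-method channelLabels,EpochSet-method
#'   channelLabels,ContrastSet-method channelLabels,DifferenceErp-method
#'   channelLabels,ErspMap-method channelLabels,ConnectivityResult-method
#'   timesMs,EpochSet-method timesMs,ContrastSet-method
#'   timesMs,DifferenceErp-method timesMs,ErspMap-method
#'   eventTable,EcogRecording-method signalMatrix,EcogRecording-method
#'   epochData,EpochSet-method epochData,ContrastSet-method
#'   keptTrials,EpochSet-method trialCondition,EpochSet-method
#'   badChannels,EpochSet-method lC,ConnectivityResult-method
#'   nC,ConnectivityResult-method significanceMask,ConnectivityResult-method
#'   chosenOrder,OrderSelection-method netDiagnostics,TrainedNet-method
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("timesMs", function(object) standardGeneric("timesMs"))
#' @rdname accessors
#' @export
setGeneric("eventTable", function(object) standardGeneric("eventTable"))
#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(object) standardGeneric("signalMatrix"))
#' @rdname accessors
#' @export
setGeneric("epochData", function(object) standardGeneric("epochData"))
#' @rdname accessors
#' @export
setGeneric("keptTrials", function(object) standardGeneric("keptTrials"))
#' @rdname accessors
#' @export
setGeneric("trialCondition", function(object) standardGeneric("trialCondition"))
#' @rdname accessors
#' @export
setGeneric("badChannels", function(object) standardGeneric("badChannels"))
#' @rdname accessors
#' @export
setGeneric("lC", function(object) standardGeneric("lC"))
#' @rdname accessors
#' @export
setGeneric("nC", function(object) standardGeneric("nC"))
#' @rdname accessors
#' @export
setGeneric("significanceMask", function(object) standardGeneric("significanceMask"))
#' @rdname accessors
#' @export
setGeneric("chosenOrder", function(object) standardGeneric("chosenOrder"))
#' @rdname accessors
#' @export
setGeneric("netDiagnostics", function(object) standardGeneric("netDiagnostics"))

setMethod("samplingRate", "EcogRecording", function(object) object@fs)
setMethod("samplingRate", "EpochSet", function(object) object@fs)
setMethod("samplingRate", "ContrastSet", function(object) object@fs)
setMethod("samplingRate", "DifferenceErp", function(object) object@fs)

setMethod("channelLabels", "EcogRecording", function(object) object@channelLabels)
setMethod("channelLabels", "EpochSet", function(object) object@channelLabels)
setMethod("channelLabels", "ContrastSet", function(object) object@channelLabels)
setMethod("channelLabels", "DifferenceErp", function(object) object@channelLabels)
setMethod("channelLabels", "ErspMap", function(object) object@channelLabels)
setMethod("channelLabels", "ConnectivityResult", function(object) object@channelLabels)

setMethod("timesMs", "EpochSet", function(object) object@times)
setMethod("timesMs", "ContrastSet", function(object) object@times)
setMethod("timesMs", "DifferenceErp", function(object) object@times)
setMethod("timesMs", "ErspMap", function(object) object@times)

setMethod("eventTable", "EcogRecording", function(object) object@events)
setMethod("signalMatrix", "EcogRecording", function(object) object@signal)
setMethod("epochData", "EpochSet", function(object) object@data)
setMethod("epochData", "ContrastSet", function(object) object@data)
setMethod("keptTrials", "EpochSet", function(object) object@kept)
setMethod("trialCondition", "EpochSet", function(object) object@condition)
setMethod("badChannels", "EpochSet", function(object) object@badChannels)

setMethod("lC", "ConnectivityResult", function(object) object@lC)
setMethod("nC", "ConnectivityResult", function(object) object@NC)
setMethod("significanceMask", "ConnectivityResult", function(object) {
  list(lC = object@sigLC, NC = object@sigNC)
})
setMethod("chosenOrder", "OrderSelection", function(object) object@chosen)
setMethod("netDiagnostics", "TrainedNet", function(object) object@diagnostics)

setMethod("show", "EcogRecording", function(object) {
  cat(sprintf(
    "EcogRecording: %d channels x %d samples (%.1f s at %g Hz)\n",
    nrow(object@signal), ncol(object@signal),
    ncol(object@signal) / object@fs, object@fs
  ))
  cat(sprintf(
    "  events: %d (%d deviant) | subject: %s | group: %s | treatment: %s\n",
    nrow(object@events), sum(object@events$tone_type == "deviant"),
    object@meta$subject %||% "?", object@meta$group %||% "?",
    object@meta$treatment %||% "?"
  ))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "EpochSet: %d trials x %d channels x %d samples [%g, %g] ms at %g Hz\n",
    d[1], d[2], d[3], min(object@times), max(object@times), object@fs
  ))
  cat(sprintf(
    "  kept %d/%d | standard %d, deviant %d | bad channels: %s\n",
    sum(object@kept), d[1],
    sum(object@condition == "standard"), sum(object@condition == "deviant"),
    if (length(object@badChannels)) paste(object@badChannels, collapse = ",") else "none"
  ))
})

setMethod("show", "ErspMap", function(object) {
  d <- dim(object@power)
  cat(sprintf(
    "ErspMap: %d channels x %d freqs [%.2f, %.2f] Hz x %d times [%g, %g] ms\n",
    d[1], d[2], min(object@freqs), max(object@freqs),
    d[3], round(min(object@times)), round(max(object@times))
  ))
})

setMethod("show", "ContrastSet", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "ContrastSet: %d contrast trials x %d channels x %d samples at %g Hz\n",
    d[1], d[2], d[3], object@fs
  ))
})

setMethod("show", "TrainedNet", function(object) {
  cat(sprintf(
    "TrainedNet: M=%d, p=%d, %d hidden units, %d repetitions (best: #%d)\n",
    object@M, object@p, object@config$nHidden %||% 10L,
    length(object@nets), object@best
  ))
  d <- object@diagnostics
  cat(sprintf(
    "  median test MSE %.4g | median test R2 %.3f\n",
    median(d$mseTest), median(d$r2Test)
  ))
})

setMethod("show", "ConnectivityResult", function(object) {
  M <- nrow(object@lC)
  off <- !diag(M)
  cat(sprintf("ConnectivityResult: %d channels (from-row -> to-column)\n", M))
  cat(sprintf(
    "  mean off-diagonal lC %.4g, NC %.4g\n",
    mean(object@lC[off]), mean(object@NC[off])
  ))
  if (length(object@surrogate)) {
    cat(sprintf(
      "  surrogates: %d | significant at alpha=%.3g: lC %d, NC %d\n",
      object@surrogate$nSurrogates, object@alpha,
      sum(object@sigLC[off]), sum(object@sigNC[off])
    ))
  } else {
    cat("  no surrogate test attached\n")
  }
})

setMethod("show", "OrderSelection", function(object) {
  cat(sprintf(
    "OrderSelection: chosen p=%d by %s over candidates %d..%d\n",
    object@chosen, toupper(object@criterion),
    min(object@table$p), max(object@table$p)
  ))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
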