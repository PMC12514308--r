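#' Cut epochs around stimulus onsets and baseline-correct
#'
#' Segments the recording into trials on the half-open window
#' `[window[1], window[2])` ms relative to each event onset, sampled at
#' the recording rate, and subtracts the per-trial per-channel mean over
#' the half-open baseline interval (default `[-100, 0)` ms). Events whose
#' window does not fit inside the recording are dropped and listed in the
#' epoch metadata.
#'
#' @param recording an [EcogRecording-class] (normally already filtered).
#' @param window epoch window in ms relative to onset, default
#'   `c(-100, 700)`.
#' @param baseline baseline interval in ms, default `c(-100, 0)`.
#' @return an [EpochSet-class]; at 3 kHz the default window gives 2400
#'   samples per epoch.
#' @export
epochAndBaseline <- function(recording, window = c(-100, 700),
                             baseline = c(-100, 0)) {
  stopifnot(is(recording, "EcogRecording"))
  events <- eventTable(recording)
  stopIfNot(nrow(events) > 0, "recording has no events")
  fs <- samplingRate(recording)
  i0 <- as.integer(round(window[1] / 1000 * fs))
  i1 <- as.integer(round(window[2] / 1000 * fs)) - 1L  # half-open upper end
  rel <- i0:i1
  times <- rel / fs * 1000
  n <- ncol(recording@signal)
  onsetIdx <- as.integer(round(events$onset * fs)) + 1L
  ok <- (onsetIdx + i0) >= 1L & (onsetIdx + i1) <= n
  dropped <- which(!ok)
  stopIfNot(any(ok), "no event window fits inside the recording")
  keep <- which(ok)
  nCh <- nrow(recording@signal)
  dat <- array(0, c(length(keep), nCh, length(rel)))
  for (t in seq_along(keep)) {
    dat[t, , ] <- recording@signal[, onsetIdx[keep[t]] + rel, drop = FALSE]
  }
  dat <- baselineCorrect(dat, times, baseline)
  new("EpochSet",
    data = dat, times = times,
    condition = factor(events$tone_type[keep], levels = c("standard", "deviant")),
    kept = rep(TRUE, length(keep)),
    fs = fs, channelLabels = channelLabels(recording),
    badChannels = character(), interpolated = character(),
    gridXY = recording@gridXY,
    meta = c(recording@meta, list(
      droppedEvents = dropped, window = window, baseline = baseline,
      eventIndex = keep
    ))
  )
}

## Subtract the per-trial per-channel mean over the half-open baseline.
baselineCorrect <- function(dat, times, baseline = c(-100, 0)) {
  bidx <- which(times >= baseline[1] & times < baseline[2])
  if (!length(bidx)) return(dat)
  bl <- apply(dat[, , bidx, drop = FALSE], c(1, 2), mean)
  sweep(dat, c(1, 2), bl, "-")
}

#' Reject artifact trials by the peak-to-peak delta criterion
#'
#' A trial is rejected when the within-epoch max-minus-min range strictly
#' exceeds `deltaCriterion` on any retained channel. A channel whose own
#' exceedance rate across trials is above `badChannelRate` is first marked
#' bad and excluded from the trial decision. The rejection log (trial,
#' channel, range) is stored in the metadata and returned attribute.
#'
#' @param epochs an [EpochSet-class].
#' @param deltaCriterion peak-to-peak threshold in microvolts (default
#'   500).
#' @param badChannelRate exceedance-rate threshold above which a channel
#'   is marked bad (default 0.5).
#' @return the [EpochSet-class] with the `kept` mask, `badChannels` and
#'   `meta$rejectionLog` updated.
#' @export
rejectArtifacts <- function(epochs, deltaCriterion = 500,
                            badChannelRate = 0.5) {
  stopifnot(is(epochs, "EpochSet"))
  stopIfNot(deltaCriterion > 0, "deltaCriterion must be positive")
  d <- epochs@data
  nT <- dim(d)[1]; nCh <- dim(d)[2]
  rng <- matrix(0, nT, nCh)
  for (ch in seq_len(nCh)) {
    m <- d[, ch, , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = nT)
    rng[, ch] <- apply(m, 1, max) - apply(m, 1, min)
  }
  exceed <- rng > deltaCriterion
  chRate <- colMeans(exceed)
  bad <- epochs@channelLabels[chRate > badChannelRate]
  retained <- !(epochs@channelLabels %in% bad)
  rejTrial <- rowSums(exceed[, retained, drop = FALSE]) > 0
  log <- which(exceed[, retained, drop = FALSE] > 0, arr.ind = TRUE)
  logDf <- data.frame(
    trial = if (nrow(log)) log[, 1] else integer(),
    channel = if (nrow(log)) epochs@channelLabels[retained][log[, 2]] else character(),
    range_uV = if (nrow(log)) rng[, retained, drop = FALSE][log] else numeric()
  )
  epochs@kept <- epochs@kept & !rejTrial
  epochs@badChannels <- union(epochs@badChannels, bad)
  epochs@meta$rejectionLog <- logDf
  epochs@meta$deltaCriterion <- deltaCriterion
  epochs
}

#' Interpolate a bad channel by inverse-distance weighting
#'
#' Replaces the named channel by the inverse-distance-weighted (power 2)
#' average of the good channels on the planar grid; for the centre
#' channel of a linear gradient field on the 3 x 3 grid this recovers the
#' true signal exactly by symmetry. The channel is recorded in the
#' `interpolated` slot and removed from `badChannels`.
#'
#' @param epochs an [EpochSet-class] with grid coordinates.
#' @param badChannel channel label to replace.
#' @param power inverse-distance power (default 2).
#' @return the updated [EpochSet-class].
#' @export
interpolateChannel <- function(epochs, badChannel, power = 2) {
  stopifnot(is(epochs, "EpochSet"))
  stopIfNot(badChannel %in% epochs@channelLabels, "unknown channel label")
  good <- setdiff(epochs@channelLabels, union(epochs@badChannels, badChannel))
  stopIfNot(length(good) >= 3, "need at least 3 good channels to interpolate")
  xy <- epochs@gridXY
  rownames(xy) <- epochs@channelLabels
  dist <- sqrt(rowSums((xy[good, , drop = FALSE] -
    matrix(xy[badChannel, ], length(good), 2, byrow = TRUE))^2))
  w <- 1 / dist^power
  w <- w / sum(w)
  bi <- match(badChannel, epochs@channelLabels)
  gi <- match(good, epochs@channelLabels)
  acc <- array(0, dim(epochs@data)[c(1, 3)])
  for (g in seq_along(gi)) {
    acc <- acc + w[g] * epochs@data[, gi[g], ]
  }
  epochs@data[, bi, ] <- acc
  epochs@badChannels <- setdiff(epochs@badChannels, badChannel)
  epochs@interpolated <- union(epochs@interpolated, badChannel)
  epochs@meta$interpolationWeights <- setNames(w, good)
  epochs
}
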