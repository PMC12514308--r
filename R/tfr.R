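#' Frequency bands for event-related oscillation features
#'
#' delta 1-4, theta 4-8, alpha 8-12, beta 12-30, gamma 30-45 Hz, the
#' low/mid/high beta subranges (12-15, 15-18, 18-30 Hz), and the whole
#' 1-45 Hz analysis range.
#'
#' @return named list of `c(lo, hi)` ranges in Hz.
#' @export
erspBands <- function() {
  list(
    delta = c(1, 4), theta = c(4, 8), alpha = c(8, 12),
    beta = c(12, 30), gamma = c(30, 45),
    low_beta = c(12, 15), mid_beta = c(15, 18), high_beta = c(18, 30),
    whole = c(1, 45)
  )
}

#' Event-related spectral perturbation (ERSP) maps
#'
#' Sliding Hann-tapered FFT of every kept trial (window of
#' `windowSamples` points, zero-padded by `padRatio`), per-trial power
#' averaged over trials per condition, then expressed in dB
#' (`10*log10` power ratio) relative to the mean pre-stimulus baseline
#' power per frequency (windows whose centre lies at or before 0 ms).
#' The underlying power is density-normalised (microvolt^2/Hz); the
#' normalisation cancels in the baseline ratio. Output is cropped to
#' 1-45 Hz. Frequencies below the window's native resolution come from
#' the zero-padded grid and are therefore spectrally smoothed.
#'
#' @param epochs an [EpochSet-class].
#' @param windowSamples FFT window length in samples; default scales the
#'   400-point window at 3 kHz to the epoch sampling rate.
#' @param padRatio zero-padding factor, a power of two (default 64).
#' @param nTimes number of output time points (window positions spread
#'   evenly over the epoch, default 200).
#' @return list of [ErspMap-class] objects: `standard`, `deviant`, and
#'   `contrast` (deviant minus standard, in dB).
#' @export
computeErsp <- function(epochs, windowSamples = NULL, padRatio = 64,
                        nTimes = 200) {
  stopifnot(is(epochs, "EpochSet"))
  fs <- epochs@fs
  if (is.null(windowSamples)) windowSamples <- as.integer(round(400 * fs / 3000))
  Tn <- dim(epochs@data)[3]
  stopIfNot(windowSamples <= Tn, "epoch shorter than the analysis window")
  stopIfNot(padRatio >= 1 && bitwAnd(padRatio, padRatio - 1L) == 0,
            "padRatio must be a power of two")
  win <- as.integer(windowSamples)
  nfft <- win * padRatio
  taper <- 0.5 * (1 - cos(2 * pi * (seq_len(win) - 1) / (win - 1)))
  freqsAll <- (0:(nfft %/% 2)) * fs / nfft
  sel <- which(freqsAll >= 1 & freqsAll <= 45)
  freqs <- freqsAll[sel]
  ## complex DFT at the selected padded bins, taper folded in
  ang <- 2 * pi * outer(sel - 1, 0:(win - 1)) / nfft
  Wr <- cos(ang) * rep(taper, each = length(sel))
  Wi <- -sin(ang) * rep(taper, each = length(sel))
  psdNorm <- 1 / (fs * sum(taper^2))

  starts <- unique(as.integer(round(seq(1, Tn - win + 1, length.out = nTimes))))
  centers <- epochs@times[starts] + (win / 2 - 0.5) / fs * 1000
  baseHops <- which(centers <= 0)
  stopIfNot(length(baseHops) > 0,
            "no analysis window centred in the pre-stimulus baseline")

  nCh <- dim(epochs@data)[2]
  condPower <- function(cond) {
    idx <- which(epochs@condition == cond & epochs@kept)
    stopIfNot(length(idx) > 0, sprintf("no kept '%s' trials", cond))
    pw <- array(0, c(nCh, length(sel), length(starts)))
    for (ch in seq_len(nCh)) {
      E <- t(epochs@data[idx, ch, , drop = TRUE])
      if (is.null(dim(E))) E <- matrix(E, ncol = 1)
      for (h in seq_along(starts)) {
        S <- E[starts[h]:(starts[h] + win - 1L), , drop = FALSE]
        P <- (Wr %*% S)^2 + (Wi %*% S)^2
        pw[ch, , h] <- rowMeans(P) * psdNorm
      }
    }
    pw
  }
  toDb <- function(pw) {
    base <- apply(pw[, , baseHops, drop = FALSE], c(1, 2), mean)
    base[base <= 0] <- .Machine$double.xmin
    10 * log10(sweep(pw, c(1, 2), base, "/"))
  }
  mkMap <- function(db) {
    new("ErspMap",
      power = db, freqs = freqs, times = centers,
      channelLabels = epochs@channelLabels,
      params = list(windowSamples = win, padRatio = padRatio,
                    taper = "hann", fs = fs, nTimes = length(starts))
    )
  }
  stdDb <- toDb(condPower("standard"))
  devDb <- toDb(condPower("deviant"))
  contrast <- mkMap(devDb - stdDb)
  list(standard = mkMap(stdDb), deviant = mkMap(devDb), contrast = contrast)
}

#' Per-band maxima of an ERSP map
#'
#' For every channel and band: the maximum dB value over post-stimulus
#' times (>= 0 ms) and in-band frequencies, with its latency and
#' frequency. Ties are broken by earliest time, then lowest frequency.
#'
#' @param ersp an [ErspMap-class].
#' @param bands named list of frequency ranges, default [erspBands()].
#' @return data.frame (`channel`, `band`, `max_db`, `latency_ms`,
#'   `freq_hz`).
#' @export
bandFeatures <- function(ersp, bands = erspBands()) {
  stopifnot(is(ersp, "ErspMap"))
  tidx <- which(ersp@times >= 0)
  rows <- list()
  for (ch in seq_along(ersp@channelLabels)) {
    for (b in names(bands)) {
      fr <- bands[[b]]
      fidx <- which(ersp@freqs >= fr[1] & ersp@freqs <= fr[2])
      stopIfNot(length(fidx) > 0, sprintf(
        "band %s [%g, %g] Hz is empty on this frequency axis", b, fr[1], fr[2]
      ))
      sub <- ersp@power[ch, fidx, tidx, drop = FALSE][1, , ]
      if (is.null(dim(sub))) sub <- matrix(sub, nrow = length(fidx))
      mx <- max(sub)
      cand <- which(sub == mx, arr.ind = TRUE)   # rows: freq, col: time
      cand <- cand[order(cand[, 2], cand[, 1]), , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        channel = ersp@channelLabels[ch], band = b, max_db = mx,
        latency_ms = ersp@times[tidx[cand[1, 2]]],
        freq_hz = ersp@freqs[fidx[cand[1, 1]]]
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
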