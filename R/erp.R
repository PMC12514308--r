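#' Condition averages and the deviant-minus-standard difference wave
#'
#' Per-channel arithmetic means over kept trials of each condition, and
#' their difference (deviant minus standard), the waveform on which ERP
#' components are detected.
#'
#' @param epochs an [EpochSet-class] with at least one kept trial per
#'   condition.
#' @return list with elements `standard` and `deviant` (channels x time
#'   matrices) and `difference` (a [DifferenceErp-class]).
#' @export
averageAndDifference <- function(epochs) {
  stopifnot(is(epochs, "EpochSet"))
  avg <- lapply(c(standard = "standard", deviant = "deviant"), function(cond) {
    idx <- which(epochs@condition == cond & epochs@kept)
    if (!length(idx)) {
      stop(sprintf("no kept trials in condition '%s'", cond), call. = FALSE)
    }
    m <- apply(epochs@data[idx, , , drop = FALSE], c(2, 3), mean)
    rownames(m) <- epochs@channelLabels
    m
  })
  diffw <- new("DifferenceErp",
    data = avg$deviant - avg$standard,
    times = epochs@times,
    channelLabels = epochs@channelLabels,
    fs = epochs@fs,
    provenance = list(
      subject = epochs@meta$subject,
      treatment = epochs@meta$treatment,
      nStandard = sum(epochs@condition == "standard" & epochs@kept),
      nDeviant = sum(epochs@condition == "deviant" & epochs@kept)
    )
  )
  list(standard = avg$standard, deviant = avg$deviant, difference = diffw)
}

#' Grand average across subjects
#'
#' Unweighted mean of per-subject averages (matrices on identical time
#' axes).
#'
#' @param waves list of channels x time matrices or
#'   [DifferenceErp-class] objects.
#' @return channels x time matrix.
#' @export
grandAverage <- function(waves) {
  mats <- lapply(waves, function(w) if (is(w, "DifferenceErp")) w@data else w)
  Reduce(`+`, mats) / length(mats)
}

#' ERP component detection windows (ms)
#'
#' P1 20-80, N1 60-150, P2 70-250, N2 100-330, P3 130-600 ms; positive
#' components are window maxima, negative components window minima.
#'
#' @return named list of `c(lo, hi)` windows in ms.
#' @export
erpWindows <- function() {
  list(
    P1 = c(20, 80), N1 = c(60, 150), P2 = c(70, 250),
    N2 = c(100, 330), P3 = c(130, 600)
  )
}

#' Detect ERP component peaks on a difference wave
#'
#' Per channel and component: the global extremum of the waveform inside
#' the component window (maximum for P components, minimum for N
#' components), ties broken by the earliest time; the amplitude is read at
#' the detected latency.
#'
#' @param wave a [DifferenceErp-class] (or a channels x time matrix with
#'   a `times` attribute) covering all component windows.
#' @param windows named list of windows, default [erpWindows()].
#' @return data.frame (`component`, `channel`, `latency_ms`,
#'   `amplitude_uV`).
#' @export
detectPeaks <- function(wave, windows = erpWindows()) {
  if (is(wave, "DifferenceErp")) {
    data <- wave@data; times <- wave@times; labels <- wave@channelLabels
  } else {
    data <- wave; times <- attr(wave, "times")
    labels <- rownames(wave) %||% as.character(seq_len(nrow(wave)))
  }
  res <- list()
  for (comp in names(windows)) {
    w <- windows[[comp]]
    idx <- which(times >= w[1] & times <= w[2])
    stopIfNot(length(idx) > 0, sprintf(
      "component window %s [%g, %g] ms lies outside the epoch", comp, w[1], w[2]
    ))
    isPos <- startsWith(comp, "P")
    for (ch in seq_len(nrow(data))) {
      seg <- data[ch, idx]
      k <- if (isPos) which.max(seg) else which.min(seg)  # first index on ties
      res[[length(res) + 1L]] <- data.frame(
        component = comp, channel = labels[ch],
        latency_ms = times[idx[k]], amplitude_uV = seg[k]
      )
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Peak-to-peak amplitudes from a component peak table
#'
#' Signed spans between successive components, positive under canonical
#' morphology: `P1N1 = amp(P1) - amp(N1)`, `N1P2 = amp(P2) - amp(N1)`,
#' `P2N2 = amp(P2) - amp(N2)`, `N2P3 = amp(P3) - amp(N2)`.
#'
#' @param peaks peak table from [detectPeaks()] containing all five
#'   components for every channel.
#' @return the peak table with the four peak-to-peak rows appended
#'   (`latency_ms` is `NA` for span rows).
#' @export
peakToPeak <- function(peaks) {
  pairs <- list(
    P1N1 = c("P1", "N1"), N1P2 = c("P2", "N1"),
    P2N2 = c("P2", "N2"), N2P3 = c("P3", "N2")
  )
  channels <- unique(peaks$channel)
  amp <- function(comp, ch) {
    v <- peaks$amplitude_uV[peaks$component == comp & peaks$channel == ch]
    stopIfNot(length(v) == 1, sprintf(
      "missing component %s for channel %s", comp, ch
    ))
    v
  }
  rows <- list()
  for (nm in names(pairs)) {
    pr <- pairs[[nm]]
    for (ch in channels) {
      rows[[length(rows) + 1L]] <- data.frame(
        component = nm, channel = ch, latency_ms = NA_real_,
        amplitude_uV = amp(pr[1], ch) - amp(pr[2], ch)
      )
    }
  }
  out <- rbind(peaks, do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
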