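#' Write / read a recording in the plain-text session layout
#'
#' A session directory holds `signal.tsv` (samples x channels, header =
#' channel labels, microvolts), `events.tsv` (BIDS-style: `onset`,
#' `duration`, `trial_type` plus tone columns), `channels.tsv` (`name`,
#' `x_mm`, `y_mm`) and `meta.json` (sampling rate and subject metadata).
#'
#' @param recording an [EcogRecording-class].
#' @param dir target directory (created if missing).
#' @return `writeRecording` the directory path, invisibly;
#'   `readRecording` the reconstructed [EcogRecording-class].
#' @export
writeRecording <- function(recording, dir) {
  stopifnot(is(recording, "EcogRecording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sig <- as.data.frame(t(recording@signal))
  names(sig) <- recording@channelLabels
  data.table::fwrite(sig, file.path(dir, "signal.tsv"), sep = "\t")
  ev <- recording@events
  events <- data.frame(
    onset = ev$onset, duration = ev$duration, trial_type = ev$tone_type,
    tone_freq = ev$tone_freq, level = ev$level, block = ev$block
  )
  data.table::fwrite(events, file.path(dir, "events.tsv"), sep = "\t")
  chan <- data.frame(
    name = recording@channelLabels,
    x_mm = recording@gridXY[, 1], y_mm = recording@gridXY[, 2]
  )
  data.table::fwrite(chan, file.path(dir, "channels.tsv"), sep = "\t")
  meta <- c(list(fs = recording@fs), recording@meta)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' @rdname writeRecording
#' @export
readRecording <- function(dir) {
  sig <- data.table::fread(file.path(dir, "signal.tsv"), sep = "\t",
                           data.table = FALSE)
  ev <- data.table::fread(file.path(dir, "events.tsv"), sep = "\t",
                          data.table = FALSE)
  chan <- data.table::fread(file.path(dir, "channels.tsv"), sep = "\t",
                            data.table = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  events <- data.frame(
    onset = ev$onset, tone_type = ev$trial_type, tone_freq = ev$tone_freq,
    level = ev$level, duration = ev$duration, block = ev$block
  )
  xy <- as.matrix(chan[, c("x_mm", "y_mm")])
  rownames(xy) <- chan$name
  fs <- meta$fs
  meta$fs <- NULL
  new("EcogRecording",
    signal = t(as.matrix(sig)), fs = fs, channelLabels = chan$name,
    gridXY = xy, events = events, meta = as.list(meta)
  )
}

#' Export an ERSP map as a long-format CSV table
#'
#' One row per (channel, frequency, time) cell with the dB value.
#'
#' @param ersp an [ErspMap-class].
#' @param file output CSV path.
#' @return invisibly, the path.
#' @export
writeErspMap <- function(ersp, file) {
  stopifnot(is(ersp, "ErspMap"))
  d <- dim(ersp@power)
  long <- data.frame(
    channel = rep(ersp@channelLabels, times = d[2] * d[3]),
    freq_hz = rep(rep(ersp@freqs, each = d[1]), times = d[3]),
    time_ms = rep(ersp@times, each = d[1] * d[2]),
    ersp_db = as.vector(ersp@power)
  )
  data.table::fwrite(long, file)
  invisible(file)
}

#' Export a connectivity result as CSV tables
#'
#' Writes the lC and NC matrices with channel-label headers plus a
#' long-format table (`from`, `to`, `lC`, `NC`, `p_lC`, `p_NC`,
#' `sig_lC`, `sig_NC`).
#'
#' @param result a [ConnectivityResult-class].
#' @param dir output directory.
#' @param prefix filename prefix.
#' @return invisibly, the paths written.
#' @export
writeConnectivity <- function(result, dir, prefix = "connectivity") {
  stopifnot(is(result, "ConnectivityResult"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lab <- result@channelLabels
  paths <- character()
  for (what in c("lC", "NC")) {
    m <- slot(result, what)
    df <- data.frame(from = lab, as.data.frame(m))
    names(df) <- c("from", lab)
    f <- file.path(dir, sprintf("%s_%s.csv", prefix, what))
    data.table::fwrite(df, f)
    paths <- c(paths, f)
  }
  M <- length(lab)
  idx <- which(!diag(M), arr.ind = TRUE)
  long <- data.frame(
    from = lab[idx[, 1]], to = lab[idx[, 2]],
    lC = result@lC[idx], NC = result@NC[idx],
    p_lC = result@pLC[idx], p_NC = result@pNC[idx],
    sig_lC = result@sigLC[idx], sig_NC = result@sigNC[idx]
  )
  f <- file.path(dir, sprintf("%s_long.csv", prefix))
  data.table::fwrite(long, f)
  paths <- c(paths, f)
  if (!is.null(result@meta$diagnostics)) {
    fd <- file.path(dir, sprintf("%s_diagnostics.json", prefix))
    jsonlite::write_json(
      list(
        perRepetition = result@meta$diagnostics,
        surrogates = result@surrogate$nSurrogates %||% 0,
        alpha = result@alpha
      ),
      fd, auto_unbox = TRUE, digits = NA, dataframe = "rows", null = "null"
    )
    paths <- c(paths, fd)
  }
  invisible(paths)
}
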