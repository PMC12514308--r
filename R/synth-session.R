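#' Parameter set of the session generator for a group/treatment preset
#'
#' Returns the full parameter list driving [simulateSession()]:
#' evoked-component templates (Gaussian-windowed deflections per ERP
#' component, separate standard/deviant amplitudes), band-limited
#' oscillatory bursts (Gaussian-windowed sinusoids per band), 1/f
#' background and sensor-noise levels, and per-channel gains.
#'
#' The four presets encode the qualitative group and stimulation effects:
#' relative to `control_pre`, `alcohol_pre` has smaller P1/N1 (hence
#' smaller P1N1 and N1P2 spans), a deeper N2 (larger P2N2), weaker
#' delta-to-beta and stronger gamma bursts, and a beta burst carrier
#' shifted from 14 to 19 Hz. The `_post` presets scale amplitudes and
#' burst powers up, with the alcohol_post enhancement weaker overall and
#' concentrated at the frontocentral (FC) electrode. Effect magnitudes are
#' generator calibration knobs, not measured quantities.
#'
#' @param preset one of `"control_pre"`, `"control_post"`,
#'   `"alcohol_pre"`, `"alcohol_post"`.
#' @return named list with elements `components`, `bursts`,
#'   `backgroundSd`, `backgroundChi`, `sensorNoiseSd`, `trialJitterSd`,
#'   `channelGain`.
#' @export
sessionPresets <- function(preset = c("control_pre", "control_post",
                                      "alcohol_pre", "alcohol_post")) {
  preset <- match.arg(preset)
  ## base (control_pre) evoked components; latencies inside the detection
  ## windows P1 20-80, N1 60-150, P2 70-250, N2 100-330, P3 130-600 ms
  ## latencies/widths chosen so each component, not a neighbour's tail, is
  ## the extremum of its own detection window on the difference wave
  comp <- data.frame(
    name = c("P1", "N1", "P2", "N2", "P3"),
    latency_ms = c(45, 85, 180, 260, 400),
    sigma_ms = c(8, 9, 20, 25, 45),
    amp_dev = c(18, -25, 12, -16, 18),
    stringsAsFactors = FALSE
  )
  comp$amp_std <- comp$amp_dev * 0.6
  ## burst widths trade time localisation against spectral footprint; wide
  ## enough that each band's feature tracks its burst, not ERP leakage
  bursts <- data.frame(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    freq = c(2.5, 6, 10, 14, 38),
    center_ms = c(300, 200, 150, 120, 90),
    sigma_ms = c(120, 80, 70, 60, 50),
    amp_dev = c(12, 9, 7, 7, 6),
    stringsAsFactors = FALSE
  )
  bursts$amp_std <- bursts$amp_dev * 0.5
  gain <- setNames(1 + 0.03 * sin(seq_len(9)), gridLabels())

  scaleErp <- function(f, which = comp$name) {
    comp[comp$name %in% which, c("amp_dev", "amp_std")] <<-
      comp[comp$name %in% which, c("amp_dev", "amp_std")] * f
  }
  ## burst effects act on the deviant response only: the baseline-ratio
  ## ERSP contrast cancels any common scaling of both conditions
  scaleBurst <- function(f, which = bursts$band) {
    bursts[bursts$band %in% which, "amp_dev"] <<-
      bursts[bursts$band %in% which, "amp_dev"] * f
  }
  if (preset %in% c("alcohol_pre", "alcohol_post")) {
    scaleErp(0.6, c("P1", "N1"))            # reduced P1N1 and N1P2
    scaleErp(1.6, "N2")                     # increased P2N2
    scaleBurst(0.7, c("delta", "theta", "alpha"))
    scaleBurst(0.85, "beta")   # power down, but the carrier dominates its band
    scaleBurst(1.5, "gamma")
    bursts$freq[bursts$band == "beta"] <- 19  # beta maximum shifted up
  }
  if (preset == "control_post") {
    scaleErp(1.5); scaleBurst(1.6)
  }
  if (preset == "alcohol_post") {
    scaleErp(1.25); scaleBurst(1.3)
    gain["FC"] <- gain["FC"] * 1.4          # enhancement concentrated at FC
  }
  list(
    preset = preset,
    components = comp,
    bursts = bursts,
    backgroundSd = 12,
    backgroundChi = 1,
    sensorNoiseSd = 3,
    trialJitterSd = 0.1,
    channelGain = gain
  )
}

#' Simulate an oddball ECoG session on the 3 x 3 grid
#'
#' Synthesises a continuous nine-channel recording: 1/f^chi background
#' noise plus white sensor noise, per-event evoked responses (sum of
#' Gaussian-windowed ERP components, deviant amplitudes larger than
#' standard), per-event band-limited oscillatory bursts, and optional
#' injected high-amplitude artifacts (> 500 microvolt peak-to-peak) at
#' known event indices. Deterministic given `(events, params, seed)`.
#'
#' @param events event table from [makeStimulusSequence()].
#' @param preset preset name passed to [sessionPresets()]; ignored when
#'   `params` is supplied.
#' @param fs sampling rate in Hz (>= 200).
#' @param seed integer seed.
#' @param params full parameter list; defaults to `sessionPresets(preset)`.
#'   Override to inject noiseless custom components in validation runs.
#' @param artifactTrials integer event indices receiving an injected
#'   artifact.
#' @param subject,group,treatment metadata; group/treatment default to the
#'   preset name parts.
#' @return an [EcogRecording-class] object.
#' @export
simulateSession <- function(events, preset = "control_pre", fs = 600,
                            seed = NULL, params = NULL,
                            artifactTrials = integer(),
                            subject = "s01", group = NULL, treatment = NULL) {
  stopIfNot(fs >= 200, "fs must be at least 200 Hz")
  if (is.null(params)) {
    valid <- c("control_pre", "control_post", "alcohol_pre", "alcohol_post")
    if (!preset %in% valid) {
      stop(sprintf(
        "unknown preset '%s'; valid presets: %s",
        preset, paste(valid, collapse = ", ")
      ), call. = FALSE)
    }
    params <- sessionPresets(preset)
  }
  if (is.null(group)) group <- sub("_.*$", "", params$preset %||% preset)
  if (is.null(treatment)) treatment <- sub("^.*_", "", params$preset %||% preset)

  nCh <- length(params$channelGain)
  labels <- names(params$channelGain)
  nSamp <- as.integer(ceiling((max(events$onset) + 1) * fs))
  tplLen <- as.integer(round(0.7 * fs))
  tplT <- (seq_len(tplLen) - 1) / fs * 1000   # ms from onset

  ## phase-locked evoked components (enter the trial-average ERP)
  template <- function(ampCol) {
    v <- numeric(tplLen)
    cp <- params$components
    if (NROW(cp)) {
      for (r in seq_len(nrow(cp))) {
        v <- v + cp[[ampCol]][r] *
          exp(-(tplT - cp$latency_ms[r])^2 / (2 * cp$sigma_ms[r]^2))
      }
    }
    v
  }
  tplStd <- template("amp_std")
  tplDev <- template("amp_dev")
  ## induced oscillatory bursts: random phase per trial, so they cancel in
  ## the averaged ERP but carry the event-related spectral power
  bs <- params$bursts
  burstS <- burstC <- NULL
  if (NROW(bs)) {
    burstS <- burstC <- matrix(0, tplLen, nrow(bs))
    for (r in seq_len(nrow(bs))) {
      env <- exp(-(tplT - bs$center_ms[r])^2 / (2 * bs$sigma_ms[r]^2))
      arg <- 2 * pi * bs$freq[r] * (tplT - bs$center_ms[r]) / 1000
      burstS[, r] <- env * sin(arg)
      burstC[, r] <- env * cos(arg)
    }
  }

  withSeed(seed, {
    sig <- matrix(0, nCh, nSamp)
    for (ch in seq_len(nCh)) {
      bg <- if (params$backgroundSd > 0) {
        oneOverFNoise(nSamp, params$backgroundChi) * params$backgroundSd
      } else 0
      wn <- if (params$sensorNoiseSd > 0) {
        rnorm(nSamp, sd = params$sensorNoiseSd)
      } else 0
      sig[ch, ] <- bg + wn
    }
    jit <- if (params$trialJitterSd > 0) {
      1 + rnorm(nrow(events), sd = params$trialJitterSd)
    } else rep(1, nrow(events))
    for (ev in seq_len(nrow(events))) {
      i0 <- round(events$onset[ev] * fs) + 1L
      idx <- i0:(i0 + tplLen - 1L)
      idx <- idx[idx <= nSamp]
      isDev <- events$tone_type[ev] == "deviant"
      tpl <- if (isDev) tplDev else tplStd
      if (!is.null(burstS)) {
        amps <- if (isDev) bs$amp_dev else bs$amp_std
        phi <- runif(nrow(bs), 0, 2 * pi)
        tpl <- tpl + burstS %*% (amps * cos(phi)) + burstC %*% (amps * sin(phi))
      }
      add <- tpl[seq_along(idx)] * jit[ev]
      for (ch in seq_len(nCh)) {
        sig[ch, idx] <- sig[ch, idx] + add * params$channelGain[ch]
      }
    }
    for (ev in artifactTrials) {
      i0 <- round(events$onset[ev] * fs) + 1L
      at <- i0 + as.integer(round(0.35 * fs))
      w <- at:min(at + as.integer(round(0.02 * fs)) + 1L, nSamp)
      half <- seq_along(w) <= length(w) / 2
      sig[, w] <- sig[, w] + rep(ifelse(half, 400, -400), each = nCh)
    }
    new("EcogRecording",
      signal = sig, fs = fs, channelLabels = labels,
      gridXY = gridCoordinates()[labels, , drop = FALSE],
      events = events,
      meta = list(
        subject = subject, group = group, treatment = treatment,
        preset = params$preset %||% preset, seed = seed,
        artifactTrials = artifactTrials
      )
    )
  })
}

## Unit-variance 1/f^chi noise via spectral shaping of white noise.
oneOverFNoise <- function(n, chi = 1) {
  nf <- stats::nextn(n, 2)
  w <- rnorm(nf)
  W <- fft(w)
  f <- c(1, seq_len(nf - 1))           # avoid the DC singularity
  f <- pmin(f, nf - f + 1)             # symmetric |frequency| index
  W <- W * (1 / f^(chi / 2))
  W[1] <- 0
  x <- Re(fft(W, inverse = TRUE)) / nf
  x <- x[seq_len(n)]
  x / sd(x)
}
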