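#' Generate a two-tone oddball stimulus sequence
#'
#' Builds the event table of a passive oddball session: tones presented at
#' a fixed stimulus-onset asynchrony (ISI + tone duration) in consecutive
#' blocks, with a configured fraction of deviant tones placed uniformly at
#' random under the constraint that no two deviants are adjacent (deviants
#' interspersed with at least one standard). The deviant count is
#' `round(deviantFraction * total)`, so the share is exact to within one
#' event. Standards are 1 kHz / 70 dB SPL, deviants 2 kHz / 80 dB SPL.
#'
#' The default session (6 blocks of 300 s, 1-s ISI, 50-ms tones) yields
#' 1716 events, 13% of them deviants.
#'
#' @param nBlocks number of blocks.
#' @param blockDuration block duration in seconds.
#' @param isi offset-to-onset interstimulus interval in seconds.
#' @param toneDuration tone duration in seconds.
#' @param deviantFraction fraction of deviant trials, in (0, 0.5).
#' @param seed integer seed; each seed gives a unique order.
#' @return data.frame with columns `onset` (s from session start),
#'   `tone_type` (`standard`/`deviant`), `tone_freq` (Hz), `level`
#'   (dB SPL), `duration` (s), `block`.
#' @examples
#' ev <- makeStimulusSequence(seed = 1)
#' nrow(ev)                       # 1716 events
#' mean(ev$tone_type == "deviant") # 0.13
#' @export
makeStimulusSequence <- function(nBlocks = 6, blockDuration = 300, isi = 1,
                                 toneDuration = 0.05, deviantFraction = 0.13,
                                 seed = NULL) {
  stopIfNot(deviantFraction > 0 && deviantFraction < 0.5,
            "deviantFraction must lie in (0, 0.5)")
  soa <- isi + toneDuration
  perBlock <- floor((blockDuration - toneDuration) / soa) + 1L
  total <- as.integer(nBlocks * perBlock)
  nDev <- as.integer(round(deviantFraction * total))
  ## k non-adjacent positions out of n exist iff k <= (n + 1) / 2
  if (nDev > (total + 1) %/% 2) {
    stop("deviant fraction too high to avoid adjacent deviants", call. = FALSE)
  }
  devPos <- withSeed(seed, sampleNonAdjacent(total, nDev))
  block <- rep(seq_len(nBlocks), each = perBlock)
  within <- rep(seq_len(perBlock) - 1L, nBlocks)
  onset <- (block - 1L) * blockDuration + within * soa
  type <- rep("standard", total)
  type[devPos] <- "deviant"
  data.frame(
    onset = onset,
    tone_type = type,
    tone_freq = ifelse(type == "deviant", 2000, 1000),
    level = ifelse(type == "deviant", 80, 70),
    duration = toneDuration,
    block = block
  )
}

## Uniform sample of k positions from 1..n with no two adjacent, via the
## standard bijection with unrestricted k-subsets of 1..(n-k+1).
sampleNonAdjacent <- function(n, k) {
  if (k == 0L) return(integer())
  base <- sort(sample.int(n - k + 1L, k))
  base + seq_len(k) - 1L
}
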