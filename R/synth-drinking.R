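#' Default alcohol-deprivation-effect drinking schedule
#'
#' Alternating free-access and deprivation phases: an initial 8-week
#' drinking phase followed by `nCycles` cycles of 14 days deprivation and
#' 21 days renewed access (a desk-scale version of the long-term
#' alternating paradigm).
#'
#' @param nCycles number of deprivation/re-access cycles.
#' @param initialDays length of the first drinking phase in days.
#' @param deprivationDays,drinkingDays phase lengths of each cycle.
#' @return data.frame with columns `phase` (label), `type`
#'   (`drinking`/`deprivation`), `days`.
#' @export
drinkingSchedule <- function(nCycles = 3, initialDays = 56,
                             deprivationDays = 14, drinkingDays = 21) {
  ph <- data.frame(
    phase = "drinking_1", type = "drinking", days = initialDays,
    stringsAsFactors = FALSE
  )
  for (k in seq_len(nCycles)) {
    ph <- rbind(
      ph,
      data.frame(
        phase = sprintf("deprivation_%d", k), type = "deprivation",
        days = deprivationDays
      ),
      data.frame(
        phase = sprintf("drinking_%d", k + 1), type = "drinking",
        days = drinkingDays
      )
    )
  }
  ph
}

#' Simulate per-rat daily drinking tables with an ADE
#'
#' Draws daily intakes (g pure ethanol / kg bodyweight) of the 5%, 10% and
#' 20% v/v solutions around configured baseline means with rat-level
#' random effects and day-level noise; on the first day after each
#' deprivation phase the intake is elevated by the configured
#' alcohol-deprivation-effect (ADE) increment. Deprivation days have zero
#' intake. Default means reproduce the reported cohort consumption
#' pattern: baseline 1.02/1.25/1.16 g/kg/day for 5/10/20% (total 3.43) and
#' ADE-day 1.58/1.49/1.59 (total 4.66).
#'
#' @param nRats number of rats.
#' @param schedule phase plan from [drinkingSchedule()].
#' @param blMeans named numeric, baseline daily intake per concentration.
#' @param adeIncrement named numeric, added to the first post-deprivation
#'   day (set to 0 for a null generator).
#' @param ratSd rat-level random-effect SD per concentration.
#' @param daySd day-level noise SD.
#' @param seed integer seed.
#' @return data.frame with columns `rat`, `day`, `phase`, `concentration`
#'   (5/10/20), `intake` (g/kg/day, non-negative).
#' @export
simulateDrinking <- function(nRats = 10, schedule = drinkingSchedule(),
                             blMeans = c(`5` = 1.02, `10` = 1.25, `20` = 1.16),
                             adeIncrement = c(`5` = 0.56, `10` = 0.24, `20` = 0.43),
                             ratSd = 0.33, daySd = 0.25, seed = NULL) {
  stopIfNot(all(blMeans > 0), "baseline means must be positive")
  stopIfNot(
    all(schedule$type %in% c("drinking", "deprivation")),
    "schedule types must be drinking/deprivation"
  )
  conc <- c(5, 10, 20)
  adeIncrement <- rep_len(adeIncrement, 3)
  withSeed(seed, {
    ratEff <- matrix(rnorm(nRats * 3, sd = ratSd), nRats, 3)
    rows <- vector("list", nRats)
    for (r in seq_len(nRats)) {
      day <- 0L
      prevType <- NA_character_
      tabs <- vector("list", nrow(schedule))
      for (ph in seq_len(nrow(schedule))) {
        nd <- schedule$days[ph]
        dayIdx <- day + seq_len(nd)
        if (schedule$type[ph] == "deprivation") {
          intake <- matrix(0, nd, 3)
        } else {
          mu <- matrix(rep(blMeans + ratEff[r, ], each = nd), nd, 3)
          if (identical(prevType, "deprivation")) {
            mu[1, ] <- mu[1, ] + adeIncrement
          }
          intake <- pmax(mu + matrix(rnorm(nd * 3, sd = daySd), nd, 3), 0)
        }
        tabs[[ph]] <- data.frame(
          rat = sprintf("rat%02d", r),
          day = rep(dayIdx, 3),
          phase = schedule$phase[ph],
          concentration = rep(conc, each = nd),
          intake = as.vector(intake)
        )
        day <- day + nd
        prevType <- schedule$type[ph]
      }
      rows[[r]] <- do.call(rbind, tabs)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
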