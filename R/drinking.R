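#' Baseline, ADE and relapse measures from a daily drinking table
#'
#' Per rat and concentration (5/10/20% and their total): `BL` is the mean
#' daily intake over the final 7 days of each free-access phase, averaged
#' across phases; `ADE` is the intake on the first day after each
#' deprivation, averaged across cycles; `relapse` is the per-cycle ADE
#' minus the immediately preceding phase's BL, averaged. Accompanied by a
#' repeated-measures ANOVA of phase (BL vs ADE) by concentration and
#' one-sample t-tests of relapse against zero per concentration and for
#' the total.
#'
#' @param table drinking table from [simulateDrinking()] (columns `rat`,
#'   `day`, `phase`, `concentration`, `intake`) with at least one
#'   completed drinking-deprivation-drinking cycle.
#' @return list: `measures` (data.frame rat x concentration with `bl`,
#'   `ade`, `relapse`), `anova` (phase x concentration rmANOVA table),
#'   `relapseTests` (one-sample t per concentration and total).
#' @export
drinkingMeasures <- function(table) {
  needed <- c("rat", "day", "phase", "concentration", "intake")
  stopIfNot(all(needed %in% names(table)), sprintf(
    "table must have columns %s", paste(needed, collapse = ", ")
  ))
  phases <- unique(table$phase[order(table$day)])
  types <- ifelse(grepl("^deprivation", phases), "deprivation", "drinking")
  stopIfNot(any(types == "deprivation"), "table contains no deprivation phase")
  ## cycles: deprivation phase followed by a drinking phase
  postDep <- which(types == "drinking" &
                     c(FALSE, head(types, -1) == "deprivation"))
  stopIfNot(length(postDep) > 0, "no completed deprivation-to-drinking cycle")
  rats <- unique(table$rat)
  concs <- sort(unique(table$concentration))
  rows <- list()
  for (r in rats) {
    tr <- table[table$rat == r, ]
    for (cc in concs) {
      trc <- tr[tr$concentration == cc, ]
      trc <- trc[order(trc$day), ]
      blByPhase <- setNames(rep(NA_real_, length(phases)), phases)
      for (ph in phases[types == "drinking"]) {
        d <- trc[trc$phase == ph, ]
        blByPhase[ph] <- mean(tail(d$intake, 7))
      }
      adeVals <- relVals <- numeric(0)
      for (k in postDep) {
        d <- trc[trc$phase == phases[k], ]
        ade <- d$intake[which.min(d$day)]
        prevBl <- blByPhase[phases[k - 2]]     # drinking phase before the deprivation
        adeVals <- c(adeVals, ade)
        relVals <- c(relVals, ade - prevBl)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        rat = r, concentration = cc,
        bl = mean(blByPhase, na.rm = TRUE),
        ade = mean(adeVals), relapse = mean(relVals)
      )
    }
  }
  meas <- do.call(rbind, rows)
  totals <- do.call(rbind, lapply(split(meas, meas$rat), function(d) {
    data.frame(rat = d$rat[1], concentration = NA,
               bl = sum(d$bl), ade = sum(d$ade), relapse = sum(d$relapse))
  }))
  rownames(totals) <- NULL
  measures <- rbind(meas, totals)
  rownames(measures) <- NULL

  long <- rbind(
    data.frame(rat = meas$rat, conc = meas$concentration,
               drinking_phase = "BL", value = meas$bl),
    data.frame(rat = meas$rat, conc = meas$concentration,
               drinking_phase = "ADE", value = meas$ade)
  )
  long$rat <- factor(long$rat)
  long$conc <- factor(long$conc)
  long$drinking_phase <- factor(long$drinking_phase, levels = c("BL", "ADE"))
  an <- if (length(rats) >= 3) {
    fit <- aov(value ~ drinking_phase * conc +
                 Error(rat / (drinking_phase * conc)), data = long)
    tidyAovStrata(summary(fit))
  } else NULL

  tests <- lapply(c(as.character(concs), "total"), function(cc) {
    v <- if (cc == "total") totals$relapse else meas$relapse[meas$concentration == as.numeric(cc)]
    if (length(v) >= 3 && sd(v) > 0) {
      tt <- t.test(v, mu = 0)
      data.frame(concentration = cc, mean = mean(v), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value)
    } else {
      data.frame(concentration = cc, mean = mean(v), t = NA, df = NA, p = NA)
    }
  })
  list(
    measures = measures,
    anova = an,
    relapseTests = do.call(rbind, tests)
  )
}

## Flatten an aov multistratum summary into a tidy F table.
tidyAovStrata <- function(sm) {
  rows <- list()
  for (stratum in sm) {
    st <- stratum[[1]]
    effs <- trimws(rownames(st))
    for (k in seq_along(effs)) {
      if (effs[k] == "Residuals") next
      rows[[length(rows) + 1L]] <- data.frame(
        effect = gsub(":", " x ", effs[k]),
        dfNum = st$Df[k],
        dfDen = st$Df[effs == "Residuals"],
        F = st$`F value`[k],
        p = st$`Pr(>F)`[k]
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
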