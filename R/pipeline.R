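#' Pipeline configuration
#'
#' Nested configuration of the end-to-end run. The `default` profile uses
#' the full protocol parameters (3 kHz sampling, 6 five-minute blocks,
#' 0.1-45 Hz Kaiser FIR with ripple 0.001, 500 microvolt delta criterion,
#' order-8 nMVAR with 10 hidden units and 100 surrogates). The `smoke`
#' profile is a reduced configuration for desk-scale end-to-end runs:
#' 600 Hz, 2 blocks, 2 subjects per group, 20 surrogates, a capped trial
#' and epoch budget.
#'
#' @param profile `"default"` or `"smoke"`.
#' @param ... named overrides of top-level sections (each a list merged
#'   over the profile values), e.g. `synth = list(nPerGroup = 4)`.
#' @return nested named list with sections `synth`, `preprocess`, `tfr`,
#'   `ncreann`, `stats`, `drinking`.
#' @export
pipelineConfig <- function(profile = c("default", "smoke"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    synth = list(
      fs = 3000, nBlocks = 6, blockDuration = 300, isi = 1,
      toneDuration = 0.05, deviantFraction = 0.13, nPerGroup = 10
    ),
    preprocess = list(
      low = 0.1, high = 45, ripple = 0.001, transitionWidth = 0.2,
      deltaCriterion = 500, badChannelRate = 0.5
    ),
    tfr = list(windowSamples = NULL, padRatio = 64, nTimes = 200),
    ncreann = list(
      p = 8, nHidden = 10, momentum = 0.9, eta0 = 0.01, maxEpochs = 200,
      patience = 6, nReps = 10, nSurrogates = 100,
      surrogateMaxEpochs = NULL, surrogateReps = NULL, maxTrials = NULL,
      minElectrodes = 8, band = "broadband", treatment = "post"
    ),
    stats = list(alpha = 0.05, fdr = TRUE),
    drinking = list(nRats = 10)
  )
  if (profile == "smoke") {
    cfg$synth$fs <- 600
    cfg$synth$nBlocks <- 2
    cfg$synth$nPerGroup <- 2
    cfg$preprocess$transitionWidth <- 1
    cfg$tfr$nTimes <- 60
    cfg$ncreann$maxEpochs <- 30
    cfg$ncreann$patience <- 4
    cfg$ncreann$nReps <- 3
    cfg$ncreann$nSurrogates <- 20
    cfg$ncreann$surrogateMaxEpochs <- 8
    cfg$ncreann$surrogateReps <- 1
    cfg$ncreann$maxTrials <- 16
    cfg$ncreann$rowSubsample <- 5000
  }
  over <- list(...)
  for (sec in names(over)) {
    stopIfNot(sec %in% names(cfg), sprintf("unknown config section '%s'", sec))
    if (is.list(over[[sec]])) {
      for (nm in names(over[[sec]])) cfg[[sec]][[nm]] <- over[[sec]][[nm]]
    } else {
      cfg[[sec]] <- over[[sec]]
    }
  }
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Sections and keys mirror [pipelineConfig()]; values present in the
#' file override the chosen profile's defaults.
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  profile <- raw$profile %||% "default"
  raw$profile <- NULL
  do.call(pipelineConfig, c(list(profile = profile), raw))
}

#' Run the full simulate-preprocess-features-connectivity-stats pipeline
#'
#' Simulates a cohort of oddball sessions (control/alcohol groups, pre-
#' and post-stimulation presets), preprocesses each session (Kaiser FIR
#' band-pass, epoching, baseline, delta-criterion artifact rejection),
#' extracts ERP peak/peak-to-peak and ERSP band features, imputes missing
#' feature cells, runs the group statistics (per-measure mixed ANOVA with
#' FDR across measures, channelwise paired t-tests between treatments),
#' estimates per-subject directed connectivity on the configured
#' treatment's sessions (subjects under the minimum-electrode rule are
#' excluded and logged), compares lC/NC per connection between groups by
#' Mann-Whitney with rank-biserial effect sizes, and computes the
#' drinking measures. All result tables are written as CSV, plus a JSON
#' run log with seeds and exclusions. Deterministic given `seed`.
#'
#' @param config configuration from [pipelineConfig()].
#' @param seed integer master seed.
#' @param outDir output directory.
#' @param verbose print stage progress.
#' @return invisibly, a list with all result objects.
#' @export
runPipeline <- function(config = pipelineConfig("smoke"), seed = 1,
                        outDir = tempfile("ncreann_run_"), verbose = FALSE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, subject, expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, "ncreann_subject_excluded")) stop(e)
      stop(sprintf("stage '%s' failed for subject %s: %s",
                   name, subject, conditionMessage(e)), call. = FALSE)
    })
  }
  sy <- config$synth
  pp <- config$preprocess
  nc <- do.call(connectivityConfig, config$ncreann[
    setdiff(names(config$ncreann), c("band", "treatment"))
  ])
  seeds <- childSeeds(seed, 1000L)
  si <- 0L
  nextSeed <- function() {
    si <<- si + 1L
    seeds[si]
  }
  kernel <- designBandpassFir(sy$fs, pp$low, pp$high, pp$ripple,
                              pp$transitionWidth)
  groups <- c("control", "alcohol")
  featRows <- list()
  connResults <- list()
  exclusions <- list()
  subjects <- character()
  epochsForConn <- list()
  for (g in groups) {
    for (i in seq_len(sy$nPerGroup)) {
      subj <- sprintf("%s%02d", substr(g, 1, 1), i)
      subjects <- c(subjects, subj)
      for (tr in c("pre", "post")) {
        say("simulating %s / %s", subj, tr)
        events <- makeStimulusSequence(
          sy$nBlocks, sy$blockDuration, sy$isi, sy$toneDuration,
          sy$deviantFraction, seed = nextSeed()
        )
        rec <- stage("simulate", subj, simulateSession(
          events, preset = sprintf("%s_%s", g, tr), fs = sy$fs,
          seed = nextSeed(), subject = subj
        ))
        rec <- stage("filter", subj, applyFilter(rec, kernel))
        ep <- stage("epoch", subj, epochAndBaseline(rec))
        ep <- stage("reject", subj, rejectArtifacts(
          ep, pp$deltaCriterion, pp$badChannelRate
        ))
        if (nrow(ep@meta$rejectionLog)) {
          dir.create(file.path(outDir, "rejections"), showWarnings = FALSE)
          data.table::fwrite(
            ep@meta$rejectionLog,
            file.path(outDir, "rejections",
                      sprintf("%s_%s_rejections.csv", subj, tr))
          )
        }
        say("features %s / %s (kept %d/%d trials)", subj, tr,
            sum(ep@kept), length(ep@kept))
        av <- stage("erp", subj, averageAndDifference(ep))
        pk <- peakToPeak(detectPeaks(av$difference))
        ersp <- stage("ersp", subj, computeErsp(
          ep, config$tfr$windowSamples, config$tfr$padRatio, config$tfr$nTimes
        ))
        bf <- bandFeatures(ersp$contrast)
        lat <- pk[!is.na(pk$latency_ms), ]
        blk <- rbind(
          data.frame(subject = subj, group = g, treatment = tr,
                     channel = lat$channel,
                     measure = paste0(lat$component, "_latency"),
                     value = lat$latency_ms),
          data.frame(subject = subj, group = g, treatment = tr,
                     channel = pk$channel[is.na(pk$latency_ms)],
                     measure = paste0(pk$component[is.na(pk$latency_ms)], "_amp"),
                     value = pk$amplitude_uV[is.na(pk$latency_ms)]),
          data.frame(subject = subj, group = g, treatment = tr,
                     channel = rep(bf$channel, 3),
                     measure = c(paste0(bf$band, "_maxdb"),
                                 paste0(bf$band, "_lat"),
                                 paste0(bf$band, "_freq")),
                     value = c(bf$max_db, bf$latency_ms, bf$freq_hz))
        )
        ## features of rejected channels go to the imputer
        blk$value[blk$channel %in% ep@badChannels] <- NA
        featRows[[length(featRows) + 1L]] <- blk
        if (tr == config$ncreann$treatment) epochsForConn[[subj]] <- ep
      }
    }
  }
  features <- do.call(rbind, featRows)

  ## impute any missing cells on the wide subject-session x feature matrix
  features$col <- paste(features$channel, features$measure, sep = ".")
  features$rowid <- paste(features$subject, features$treatment, sep = ".")
  wide <- tapply(features$value, list(features$rowid, features$col),
                 function(v) v[1])
  if (anyNA(wide)) {
    say("imputing %d missing feature cells", sum(is.na(wide)))
    wide <- imputeFeatures(wide, seed = nextSeed())
    features$value <- wide[cbind(features$rowid, features$col)]
  }
  features$col <- features$rowid <- NULL
  data.table::fwrite(features, file.path(outDir, "features.csv"))

  ## per-measure mixed ANOVA, FDR across measures within each effect
  anovaRows <- list()
  for (ms in unique(features$measure)) {
    tab <- features[features$measure == ms, ]
    an <- stage("stats", ms, rmAnova(tab))
    an$measure <- ms
    anovaRows[[ms]] <- an
  }
  anova <- do.call(rbind, anovaRows)
  rownames(anova) <- NULL
  if (isTRUE(config$stats$fdr)) {
    anova$pFdr <- NA_real_
    for (eff in unique(anova$effect)) {
      k <- anova$effect == eff
      anova$pFdr[k] <- fdrAdjust(anova$p[k])
    }
  }
  data.table::fwrite(anova, file.path(outDir, "anova.csv"))

  ## channelwise paired t between treatments, per measure (all subjects)
  ttRows <- list()
  for (ms in unique(features$measure)) {
    tab <- features[features$measure == ms, ]
    wPre <- tapply(tab$value[tab$treatment == "pre"],
                   list(tab$subject[tab$treatment == "pre"],
                        tab$channel[tab$treatment == "pre"]), function(v) v[1])
    wPost <- tapply(tab$value[tab$treatment == "post"],
                    list(tab$subject[tab$treatment == "post"],
                         tab$channel[tab$treatment == "post"]), function(v) v[1])
    tt <- pairedTByChannel(wPre, wPost[rownames(wPre), colnames(wPre)])
    tt$measure <- ms
    ttRows[[ms]] <- tt
  }
  pairedT <- do.call(rbind, ttRows)
  rownames(pairedT) <- NULL
  data.table::fwrite(pairedT, file.path(outDir, "paired_t.csv"))

  ## per-subject connectivity on the configured treatment's sessions
  for (subj in names(epochsForConn)) {
    say("connectivity %s", subj)
    res <- tryCatch(
      estimateConnectivity(epochsForConn[[subj]], nc, seed = nextSeed(),
                           band = config$ncreann$band),
      ncreann_subject_excluded = function(e) {
        exclusions[[subj]] <<- conditionMessage(e)
        NULL
      }
    )
    if (!is.null(res)) {
      connResults[[subj]] <- res
      writeConnectivity(res, file.path(outDir, "connectivity"),
                        prefix = subj)
    }
  }

  ## group comparison of lC/NC per connection (Mann-Whitney, rank-biserial)
  groupTests <- NULL
  if (length(connResults) >= 4) {
    isAlc <- vapply(connResults, function(r) r@meta$group == "alcohol",
                    logical(1))
    lab <- connResults[[1]]@channelLabels
    M <- length(lab)
    rows <- list()
    for (i in seq_len(M)) for (j in seq_len(M)) {
      if (i == j) next
      for (what in c("lC", "NC")) {
        va <- vapply(connResults[isAlc], function(r) slot(r, what)[i, j],
                     numeric(1))
        vc <- vapply(connResults[!isAlc], function(r) slot(r, what)[i, j],
                     numeric(1))
        mw <- mannWhitneyEffect(va, vc)
        rows[[length(rows) + 1L]] <- data.frame(
          from = lab[i], to = lab[j], matrix = what,
          U = mw$U, p = mw$p, effectSize = mw$effectSize
        )
      }
    }
    groupTests <- do.call(rbind, rows)
    if (isTRUE(config$stats$fdr)) {
      for (what in c("lC", "NC")) {
        k <- groupTests$matrix == what
        groupTests$pFdr[k] <- fdrAdjust(groupTests$p[k])
      }
    }
    data.table::fwrite(groupTests, file.path(outDir, "connectivity_group_tests.csv"))
  }

  ## drinking behaviour
  drinking <- simulateDrinking(config$drinking$nRats, seed = nextSeed())
  data.table::fwrite(drinking, file.path(outDir, "drinking.csv"))
  dm <- drinkingMeasures(drinking)
  data.table::fwrite(dm$measures, file.path(outDir, "drinking_measures.csv"))
  data.table::fwrite(dm$relapseTests, file.path(outDir, "drinking_relapse_tests.csv"))

  log <- list(
    package = as.character(utils::packageVersion("ncreann")),
    seed = seed, profile = config$profile,
    subjects = subjects,
    excluded = lapply(exclusions, function(m) "insufficient channels"),
    exclusionReasons = exclusions,
    config = config
  )
  jsonlite::write_json(log, file.path(outDir, "run_log.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(list(
    features = features, anova = anova, pairedT = pairedT,
    connectivity = connResults, groupTests = groupTests,
    drinking = dm, exclusions = exclusions, outDir = outDir
  ))
}
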