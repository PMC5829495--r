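# End-to-end orchestration: simulate -> quantify -> fit -> report, with a
# canonical default configuration encoding the reference experiment
# (days 2/4/7/14; bundle half-life 5.5 d; biphasic surround 0.9/5.7 d with
# breakpoint day 4; bin half-lives 6.5/6.2/6.7 d; Early-On vs Late-On
# bundle incorporation; photobleach with surround-only recovery).

#' Canonical pipeline configuration
#'
#' Returns the default parameterization of the synthetic experiment as a
#' nested list (the same schema as the YAML config consumed by
#' [readPipelineConfig()] and the command-line driver). The surround
#' starting intensity is derived from the anchor that the surround's
#' per-day decline is 25-fold that of the bundle on the first observed day.
#'
#' @param seed master seed recorded in the config.
#' @return nested configuration list.
#' @export
paperDefaultConfig <- function(seed = 1L) {
  lamBundle <- log(2) / 5.5
  lamEarly <- log(2) / 0.9
  lamLate <- log(2) / 5.7
  n0Bundle <- 1000
  rateRatioDay2 <- 25
  n0Surround <- rateRatioDay2 * n0Bundle *
    (1 - exp(-lamBundle)) / (1 - exp(-lamEarly))
  list(
    seed = as.integer(seed),
    phantom = list(lengthPx = 220L, diameterPx = 15L, bundleWidthPx = 5L,
                   hillockPx = 10L, growthconePx = 10L, backgroundLevel = 50),
    binsPhantom = list(lengthPx = 220L, diameterPx = 25L, bundleWidthPx = 10L,
                       hillockPx = 10L, growthconePx = 10L,
                       backgroundLevel = 50),
    acquisition = list(gaussianReadNoiseSd = 10, poissonNoise = TRUE,
                       psfSigmaPx = 0),
    cohort = list(nCells = 30L, cellCv = 0.10, days = c(2, 4, 7, 14)),
    kinetics = list(
      bundle = list(N0 = n0Bundle, halfLifeDays = 5.5, start = 2, end = 14,
                    additive = TRUE),
      surround = list(N0 = n0Surround, earlyHalfLifeDays = 0.9,
                      lateHalfLifeDays = 5.7, breakDay = 4, start = 2,
                      end = 14)),
    bins = list(days = c(4, 7, 14), N0 = n0Bundle,
                spatialProfile = c(0.7, 0.85, 1.0, 0.85, 0.7),
                halfLives = list(center = 6.5, interior = 6.2, edge = 6.7),
                start = 4, end = 14),
    earlyLate = list(nCells = 30L, earlyDay = 2, lateDay = 4,
                     lateIncorporation = 0.35,
                     lateSpatialProfile = c(1.3, 1.1, 0.2, 1.1, 1.3)),
    bleach = list(nCells = 5L, preDay = 4.99, bleachDay = 5,
                  recoveredDay = 5.5, regionStartPx = 80L,
                  regionEndPx = 140L, efficiency = 0.95,
                  surroundRecoveryFraction = 0.92,
                  bundleRecoveryFraction = 0, recoveryDelayDays = 0.5),
    fit = list(breakpointDay = 4, bootstrapReps = 0L)
  )
}

#' Validate a pipeline configuration
#'
#' Checks the schema (required blocks, types, ranges) before any stage
#' runs.
#'
#' @param config nested list (see [paperDefaultConfig()]).
#' @return invisibly `TRUE`; stops with a descriptive error otherwise.
#' @export
validatePipelineConfig <- function(config) {
  need <- c("seed", "phantom", "acquisition", "cohort", "kinetics",
            "bins", "earlyLate", "bleach", "fit")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop("config schema error: missing block(s): ", paste(missing, collapse = ", "))
  co <- config$cohort
  if (!is.numeric(co$nCells) || co$nCells < 1)
    stop("config schema error: cohort$nCells must be >= 1")
  if (!is.numeric(co$cellCv) || co$cellCv < 0)
    stop("config schema error: cohort$cellCv must be >= 0")
  if (is.unsorted(co$days, strictly = TRUE))
    stop("config schema error: cohort$days must be strictly increasing")
  k <- config$kinetics
  if (is.null(k$bundle$halfLifeDays) || k$bundle$halfLifeDays <= 0)
    stop("config schema error: kinetics$bundle$halfLifeDays must be > 0")
  if (is.null(k$surround$earlyHalfLifeDays) || is.null(k$surround$lateHalfLifeDays))
    stop("config schema error: surround early/late half-lives required")
  bl <- config$bleach
  if (bl$efficiency < 0 || bl$efficiency > 1)
    stop("config schema error: bleach$efficiency must be in [0, 1]")
  invisible(TRUE)
}

#' Read and validate a YAML pipeline configuration
#'
#' @param path YAML file with the [paperDefaultConfig()] schema.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  config <- yaml::read_yaml(path)
  validatePipelineConfig(config)
  config
}

cohortKinetics <- function(config) {
  kb <- config$kinetics$bundle
  ks <- config$kinetics$surround
  list(
    CompartmentKinetics("bundle", kb$N0,
      c(kb$start, kb$end, log(2) / kb$halfLifeDays),
      additive = isTRUE(kb$additive)),
    CompartmentKinetics("surround", ks$N0, rbind(
      c(ks$start, ks$breakDay, log(2) / ks$earlyHalfLifeDays),
      c(ks$breakDay, ks$end, log(2) / ks$lateHalfLifeDays))))
}

binsKinetics <- function(config) {
  b <- config$bins
  list(
    CompartmentKinetics("bundle", b$N0,
      c(b$start, b$end, log(2) / b$halfLives$center),
      spatialProfile = b$spatialProfile,
      binLambda = log(2) / unlist(b$halfLives)[c("edge", "interior", "center",
                                                 "interior", "edge")],
      additive = TRUE),
    cohortKinetics(config)[[2L]])
}

earlyLateKinetics <- function(config, condition = c("early", "late")) {
  condition <- match.arg(condition)
  base <- cohortKinetics(config)
  if (condition == "early") return(base)
  ## Late-On expression opens later: the whole kinetics timeline is shifted
  ## so that day `lateDay` is 24 h post-expression (the reference day), the
  ## surround level then matching the Early-On surround at its reference
  ## day, while bundle incorporation is suppressed and centrally depleted.
  el <- config$earlyLate
  kb <- config$kinetics$bundle
  ks <- config$kinetics$surround
  shift <- el$lateDay - el$earlyDay
  late <- CompartmentKinetics("bundle", kb$N0 * el$lateIncorporation,
    c(kb$start + shift, kb$end + shift, log(2) / kb$halfLifeDays),
    spatialProfile = el$lateSpatialProfile, additive = TRUE)
  surround <- CompartmentKinetics("surround", ks$N0, rbind(
    c(ks$start + shift, ks$breakDay + shift, log(2) / ks$earlyHalfLifeDays),
    c(ks$breakDay + shift, ks$end + shift, log(2) / ks$lateHalfLifeDays)))
  list(late, surround)
}

#' Quantify a bleached series inside the bleached region
#'
#' Extracts lateral profiles at locations inside the bleach region for
#' every frame and returns the per-frame surround and surround-corrected
#' bundle values.
#'
#' @param stack a (bleached) [NeuriteStack-class].
#' @param bleach the [BleachSpec-class] applied.
#' @param nLocations profile locations sampled inside the region.
#' @param ... passed to [surroundCorrectedBundle()] via [measureCell()]
#'   internals (currently `halfwidthPx`, `k`).
#' @param halfwidthPx,k profile extraction/detection parameters.
#' @return data.frame `day`, `compartment`, `intensity` (GFP channel).
#' @export
quantifyBleachRegion <- function(stack, bleach, nLocations = 3L,
                                 halfwidthPx = 2L, k = 2) {
  locs <- round(bleach@regionStartPx +
    (seq_len(nLocations) - 0.5) * (bleach@regionEndPx - bleach@regionStartPx) /
    nLocations)
  out <- lapply(seq_along(stack@frames), function(f) {
    vals <- lapply(locs, function(loc) {
      prof <- extractLateralProfile(stack@frames[[f]], loc, halfwidthPx)
      ext <- detectBundleExtent(prof, k = k)
      sc <- surroundCorrectedBundle(prof, ext)
      sc[sc$channel == "gfp", c("bundle", "surround")]
    })
    bund <- mean(vapply(vals, function(v) v$bundle, numeric(1)))
    surr <- mean(vapply(vals, function(v) v$surround, numeric(1)))
    data.frame(day = stack@days[f], compartment = c("bundle", "surround"),
               intensity = c(bund, surr))
  })
  do.call(rbind, out)
}

#' Run the full synthetic experiment
#'
#' Stages, in order: (1) simulate and quantify the main cohort (bundle +
#' biphasic surround); (2) the five-bin cohort; (3) the Early-On / Late-On
#' pair; (4) the photobleach series; (5) fit all decays, compute the
#' surround/bundle per-day decline-rate ratios at the first and third
#' observed days, the Early/Late fold comparison and the recovery metrics,
#' and write the report. Stage outputs (measurement CSVs) are reused when
#' present unless `overwrite = TRUE`; every stage logs via [message()].
#'
#' @param config configuration list (see [paperDefaultConfig()]).
#' @param outDir artifact directory.
#' @param seed overrides `config$seed` when supplied.
#' @param overwrite recompute stages whose outputs already exist.
#' @param plots emit figures with the report.
#' @return invisibly, a list with the measurement tables, fits
#'   (`surroundEarly`, `surroundLate`, `bundle`, `surroundBiphasic`,
#'   per-bin fits), decline-rate ratios, Early/Late comparison and
#'   [RecoveryResult-class] objects.
#' @export
runPipeline <- function(config = paperDefaultConfig(), outDir = tempfile("bundledecay"),
                        seed = NULL, overwrite = FALSE, plots = TRUE) {
  validatePipelineConfig(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  cfgAcq <- AcquisitionConfig(
    gaussianReadNoiseSd = config$acquisition$gaussianReadNoiseSd,
    poissonNoise = config$acquisition$poissonNoise,
    psfSigmaPx = config$acquisition$psfSigmaPx, seed = config$seed)

  stageCsv <- function(name, producer) {
    path <- file.path(outDir, paste0(name, ".csv"))
    if (file.exists(path) && !overwrite) {
      message("[", name, "] reusing ", path)
      return(utils::read.csv(path))
    }
    message("[", name, "] simulating and quantifying (seed ", config$seed, ")")
    tab <- producer()
    utils::write.csv(tab, path, row.names = FALSE)
    tab
  }

  mainPhantom <- do.call(NeuritePhantom, config$phantom)
  main <- stageCsv("measurements_main", function()
    simulateCohort(mainPhantom, cohortKinetics(config), config$cohort$days,
                   nCells = config$cohort$nCells, cellCv = config$cohort$cellCv,
                   config = cfgAcq, seed = config$seed))

  binsPhantom <- do.call(NeuritePhantom, config$binsPhantom %||% config$phantom)
  binsTab <- stageCsv("measurements_bins", function()
    simulateCohort(binsPhantom, binsKinetics(config), config$bins$days,
                   nCells = config$cohort$nCells, cellCv = config$cohort$cellCv,
                   config = cfgAcq, seed = subSeed(config$seed, 101)))

  el <- config$earlyLate
  early <- stageCsv("measurements_early_on", function()
    simulateCohort(mainPhantom, earlyLateKinetics(config, "early"), el$earlyDay,
                   nCells = el$nCells, cellCv = config$cohort$cellCv,
                   config = cfgAcq, seed = subSeed(config$seed, 202)))
  late <- stageCsv("measurements_late_on", function()
    simulateCohort(mainPhantom, earlyLateKinetics(config, "late"), el$lateDay,
                   nCells = el$nCells, cellCv = config$cohort$cellCv,
                   config = cfgAcq, seed = subSeed(config$seed, 303)))

  message("[bleach] simulating photobleach-recovery series")
  bl <- config$bleach
  bleach <- BleachSpec(bl$regionStartPx, bl$regionEndPx, bl$bleachDay,
                       efficiency = bl$efficiency,
                       surroundRecoveryFraction = bl$surroundRecoveryFraction,
                       bundleRecoveryFraction = bl$bundleRecoveryFraction,
                       recoveryDelayDays = bl$recoveryDelayDays)
  bleachDays <- c(bl$preDay, bl$bleachDay, bl$recoveredDay)
  bleachVals <- lapply(seq_len(bl$nCells), function(i) {
    cfgI <- cfgAcq
    cfgI@seed <- subSeed(config$seed, 404 + i)
    st <- renderTimeSeries(mainPhantom, cohortKinetics(config), bleachDays,
                           config = cfgI, bleach = bleach)
    quantifyBleachRegion(st, bleach)
  })

  message("[fit] fitting decays and assembling the report")
  bp <- config$fit$breakpointDay
  aggS <- aggregateSeries(main, "surround")
  aggB <- aggregateSeries(main, "bundle")
  fits <- list(
    surroundBiphasic = fitBiphasic(aggS, breakpointDay = bp),
    bundle = fitExponential(aggB))
  surroundEarly <- fits$surroundBiphasic@early
  surroundLate <- fits$surroundBiphasic@late
  binFits <- perBinHalfLives(binsTab,
    window = c(config$bins$start, config$bins$end))
  names(binFits) <- paste0("bin.", names(binFits))
  fits <- c(fits, binFits)

  day1 <- min(config$cohort$days)
  day3 <- config$cohort$days[3L]
  ratios <- c(
    declineRateRatio(surroundEarly, fits$bundle, day1, method = "daily"),
    declineRateRatio(surroundLate, fits$bundle, day3, method = "daily"))
  names(ratios) <- paste0("day", c(day1, day3))

  bundleByCell <- function(tab) {
    b <- tab[tab$compartment == "bundle" & tab$channel == "gfp" &
               !is.na(tab$intensity), ]
    stats::aggregate(intensity ~ cell_id, data = b, FUN = mean)$intensity
  }
  comparison <- compareConditions(bundleByCell(early), bundleByCell(late),
    labels = c("Early-On", "Late-On"), metric = "bundle GFP")

  recScalar <- function(comp) {
    v <- vapply(bleachVals, function(tab) {
      x <- tab[tab$compartment == comp, ]
      x$intensity[order(x$day)]
    }, numeric(3L))
    rowMeans(v)
  }
  s3 <- recScalar("surround")
  b3 <- recScalar("bundle")
  recovery <- list(surround = recoveryMetrics(s3[1L], s3[2L], s3[3L]),
                   bundle = recoveryMetrics(b3[1L], b3[2L], b3[3L]))
  bleachCells <- list(
    bundlePost = vapply(bleachVals, function(tab)
      tab$intensity[tab$compartment == "bundle"][2L], numeric(1)),
    bundleRecovered = vapply(bleachVals, function(tab)
      tab$intensity[tab$compartment == "bundle"][3L], numeric(1)),
    surroundPre = vapply(bleachVals, function(tab)
      tab$intensity[tab$compartment == "surround"][1L], numeric(1)),
    surroundRecovered = vapply(bleachVals, function(tab)
      tab$intensity[tab$compartment == "surround"][3L], numeric(1)))

  buildReport(fits, list(comparison), outDir,
              measurements = list(surroundBiphasic = aggS, bundle = aggB),
              plots = plots)
  extra <- list(declineRateRatios = as.list(ratios),
                recovery = list(
                  surroundFractionOfPre = recovery$surround@fractionOfPre,
                  bundleFractionOfPre = recovery$bundle@fractionOfPre))
  jsonlite::write_json(extra, file.path(outDir, "pipeline_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(measurements = list(main = main, bins = binsTab,
                                     early = early, late = late),
                 aggregates = list(surround = aggS, bundle = aggB),
                 fits = fits, surroundEarly = surroundEarly,
                 surroundLate = surroundLate, ratios = ratios,
                 comparison = comparison, recovery = recovery,
                 bleachCells = bleachCells, outDir = outDir))
}
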