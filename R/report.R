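# Tabular and graphical reporting of fits and comparisons.

decayFitRow <- function(name, fit) {
  data.frame(name = name, window_start = fit@window[1L],
             window_end = fit@window[2L], t0 = fit@t0, n0 = fit@n0,
             lambda = fit@lambda, half_life_days = fit@halfLifeDays,
             r_squared = fit@rSquared, flag = fit@flag)
}

fitsTable <- function(fits) {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (is(f, "BiphasicFit"))
      rbind(decayFitRow(paste0(nm, ".early"), f@early),
            decayFitRow(paste0(nm, ".late"), f@late))
    else decayFitRow(nm, f)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

comparisonsTable <- function(comparisons) {
  rows <- lapply(comparisons, function(cc) {
    data.frame(metric = cc@metric,
               condition_a = cc@labels[1L], condition_b = cc@labels[2L],
               mean_a = cc@means[1L], mean_b = cc@means[2L],
               sd_a = cc@sds[1L], sd_b = cc@sds[2L],
               n_a = cc@ns[1L], n_b = cc@ns[2L],
               fold_difference = cc@foldDifference,
               t_statistic = cc@tStatistic, p_value = cc@pValue)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a deterministic report of fits and comparisons
#'
#' Emits `fits.csv`, `comparisons.csv` (when comparisons are supplied),
#' `summary.json`, and — when measurement series are supplied — decay-curve
#' plots. Given identical inputs the CSV/JSON outputs are byte-identical.
#'
#' @param fits named list of [DecayFit-class] / [BiphasicFit-class]
#'   objects.
#' @param comparisons optional list of [ConditionComparison-class].
#' @param outDir output directory (created if needed).
#' @param measurements optional named list of per-day aggregate series
#'   (matching names in `fits`) to plot under the fitted curves.
#' @param plots emit PNG figures.
#' @return invisibly, the paths written.
#' @export
buildReport <- function(fits, comparisons = list(), outDir,
                        measurements = NULL, plots = TRUE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  ft <- fitsTable(fits)
  fitsPath <- file.path(outDir, "fits.csv")
  utils::write.csv(ft, fitsPath, row.names = FALSE)
  paths <- c(paths, fitsPath)
  ct <- NULL
  if (length(comparisons)) {
    ct <- comparisonsTable(comparisons)
    cmpPath <- file.path(outDir, "comparisons.csv")
    utils::write.csv(ct, cmpPath, row.names = FALSE)
    paths <- c(paths, cmpPath)
  }
  jsonPath <- file.path(outDir, "summary.json")
  jsonlite::write_json(list(fits = ft, comparisons = ct), jsonPath,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  paths <- c(paths, jsonPath)
  if (plots && !is.null(measurements)) {
    pngPath <- file.path(outDir, "decay_curves.png")
    grDevices::png(pngPath, width = 480 * length(measurements), height = 480)
    op <- graphics::par(mfrow = c(1, length(measurements)))
    on.exit({ graphics::par(op); grDevices::dev.off() })
    for (nm in names(measurements))
      plotDecayFit(measurements[[nm]], fits[[nm]], main = nm)
    paths <- c(paths, pngPath)
  }
  invisible(paths)
}

#' Plot a lateral profile
#'
#' @param profile a [LateralProfile-class].
#' @param channel channel to plot.
#' @param ... passed to [graphics::plot()].
#' @export
plotLateralProfile <- function(profile, channel = "gfp", ...) {
  graphics::plot(profile@positionPx,
                 profile@intensity[, channelIndex(profile, channel)],
                 type = "l", xlab = "transverse position (px)",
                 ylab = "intensity (a.u.)", ...)
}

#' Plot a five-bin bundle profile
#'
#' @param binned a [BinnedBundleProfile-class].
#' @param ... passed to [graphics::barplot()].
#' @export
plotBinnedProfile <- function(binned, ...) {
  graphics::barplot(binned@bins,
                    names.arg = c("edge", "interior", "center", "interior", "edge"),
                    ylab = if (binned@normalized) "relative intensity"
                           else "intensity (a.u.)", ...)
}

#' Plot a per-day series with its fitted decay curve
#'
#' @param series per-day aggregate data.frame (`day`, `mean`, optionally
#'   `sem`).
#' @param fit a [DecayFit-class] or [BiphasicFit-class].
#' @param ... passed to [graphics::plot()].
#' @export
plotDecayFit <- function(series, fit, ...) {
  graphics::plot(series$day, series$mean, pch = 19, xlab = "day in culture",
                 ylab = "intensity (a.u.)", ...)
  if (!is.null(series$sem))
    graphics::arrows(series$day, series$mean - series$sem, series$day,
                     series$mean + series$sem, angle = 90, code = 3,
                     length = 0.03)
  drawFit <- function(f) {
    d <- seq(f@window[1L], f@window[2L], length.out = 100L)
    graphics::lines(d, f@n0 * exp(-f@lambda * (d - f@t0)), col = "red3")
  }
  if (is(fit, "BiphasicFit")) { drawFit(fit@early); drawFit(fit@late) }
  else drawFit(fit)
  invisible(NULL)
}
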