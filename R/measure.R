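# Per-cell measurement: compose profile extraction, bundle detection,
# surround correction and binning over sampled longitudinal locations per
# segment and per frame, emitting tidy per-compartment records.

#' Quantify a rendered (or acquired) neurite series
#'
#' For every frame and every proximal/central/distal segment, lateral
#' profiles are extracted at `locationsPerSegment` equally spaced
#' longitudinal locations, the bundle extent is detected on the reference
#' channel, and surround-corrected bundle, surround, and the five raw
#' (unnormalized, surround-corrected) transverse bins are computed per
#' channel and averaged over the sampled locations. Locations where no
#' bundle is detected contribute `NA` bundle/bin fields but are retained in
#' the surround records.
#'
#' @param stack a [NeuriteStack-class].
#' @param locationsPerSegment number of longitudinal sampling locations per
#'   segment (default 3).
#' @param halfwidthPx longitudinal averaging half-width of each profile.
#' @param k threshold multiplier for [detectBundleExtent()].
#' @param referenceChannel channel used for bundle detection.
#' @param subtractBackground passed to [surroundCorrectedBundle()].
#' @param bins also emit the five bin records.
#' @param cellId identifier recorded in the output.
#' @return data.frame with columns `cell_id`, `day`, `segment`, `channel`,
#'   `compartment` (`bundle`, `surround`, `bin_edge_l`, `bin_int_l`,
#'   `bin_center`, `bin_int_r`, `bin_edge_r`), `intensity`.
#' @export
measureCell <- function(stack, locationsPerSegment = 3L, halfwidthPx = 2L,
                        k = 2, referenceChannel = "phospho",
                        subtractBackground = TRUE, bins = TRUE,
                        cellId = "cell_001") {
  ph <- stack@phantom
  part <- partitionSegments(ph@lengthPx, ph@hillockPx, ph@growthconePx)
  segs <- rownames(part@bounds)
  out <- vector("list", length(stack@frames) * length(segs))
  idx <- 0L
  for (f in seq_along(stack@frames)) {
    frame <- stack@frames[[f]]
    day <- stack@days[f]
    for (s in segs) {
      b <- part@bounds[s, ]
      locs <- round(b[1L] + ((seq_len(locationsPerSegment)) - 0.5) *
                      (b[2L] - b[1L]) / locationsPerSegment)
      vals <- lapply(locs, function(loc) {
        prof <- extractLateralProfile(frame, loc, halfwidthPx)
        ext <- tryCatch(
          detectBundleExtent(prof, referenceChannel = referenceChannel, k = k),
          error = function(e) e)
        if (inherits(ext, "error")) {
          ## keep the surround usable: mean over the whole neurite interval
          surr <- vapply(prof@channelNames, function(ch) {
            v <- prof@intensity[, channelIndex(prof, ch)]
            mean(v[v > min(v)])
          }, numeric(1))
          return(list(bundle = rep(NA_real_, 2), surround = surr,
                      bins = matrix(NA_real_, nrow = 5L, ncol = 2L)))
        }
        sc <- surroundCorrectedBundle(prof, ext, subtractBackground)
        bb <- vapply(prof@channelNames, function(ch)
          binBundle(prof, ext, normalize = FALSE, channel = ch)@bins,
          numeric(5))
        ## bins reported surround- and background-corrected, like the
        ## bundle value (binBundle itself returns raw profile means)
        bb <- sweep(bb, 2L, sc$surround + sc$background, "-")
        list(bundle = sc$bundle, surround = sc$surround, bins = bb)
      })
      chans <- c("gfp", "phospho")
      rows <- lapply(seq_along(chans), function(ci) {
        bund <- mean(vapply(vals, function(v) v$bundle[ci], numeric(1)), na.rm = TRUE)
        surr <- mean(vapply(vals, function(v) v$surround[ci], numeric(1)), na.rm = TRUE)
        rec <- data.frame(
          cell_id = cellId, day = day, segment = s, channel = chans[ci],
          compartment = c("bundle", "surround"),
          intensity = c(ifelse(is.nan(bund), NA_real_, bund), surr))
        if (bins) {
          bm <- rowMeans(vapply(vals, function(v) v$bins[, ci], numeric(5)),
                         na.rm = TRUE)
          rec <- rbind(rec, data.frame(
            cell_id = cellId, day = day, segment = s, channel = chans[ci],
            compartment = binNames, intensity = as.numeric(bm)))
        }
        rec
      })
      idx <- idx + 1L
      out[[idx]] <- do.call(rbind, rows)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate and quantify a cohort of synthetic neurites
#'
#' Renders `nCells` neurites sharing phantom geometry and kinetics, each
#' with per-cell, per-day multiplicative lognormal intensity variation of
#' coefficient of variation `cellCv` (mean 1, drawn independently per
#' compartment), and runs [measureCell()] on every cell. All randomness is
#' derived from `seed`.
#'
#' @inheritParams renderTimeSeries
#' @param nCells number of cells (>= 1).
#' @param cellCv per-cell lognormal coefficient of variation (>= 0).
#' @param seed integer master seed.
#' @param ... further arguments to [measureCell()].
#' @return combined measurement data.frame (see [measureCell()]).
#' @export
simulateCohort <- function(phantom, kinetics, days, nCells = 30L,
                           cellCv = 0.10, config = AcquisitionConfig(),
                           seed = 1L, bleach = NULL, ...) {
  if (nCells < 1L) stop("nCells must be >= 1")
  if (cellCv < 0) stop("cellCv must be >= 0")
  sdlog <- sqrt(log(1 + cellCv^2))
  res <- vector("list", nCells)
  for (i in seq_len(nCells)) {
    cellSeed <- subSeed(seed, i * 1009)
    scale <- withSeed(cellSeed, matrix(
      stats::rlnorm(2L * length(days), meanlog = -sdlog^2 / 2, sdlog = sdlog),
      nrow = 2L, dimnames = list(c("bundle", "surround"), NULL)))
    cfg <- config
    cfg@seed <- cellSeed
    st <- renderTimeSeries(phantom, kinetics, days, config = cfg,
                           bleach = bleach, intensityScale = scale)
    res[[i]] <- measureCell(st, cellId = sprintf("cell_%03d", i), ...)
  }
  do.call(rbind, res)
}

#' Emit a closed-form compartment intensity table
#'
#' Fast path that bypasses image rendering: per cell and day, the bundle
#' and surround trajectories (and the five bin trajectories when per-bin
#' kinetics are present) times independent lognormal(mean 1, cv)
#' multiplicative noise.
#'
#' @param kinetics list with one `"bundle"` and one `"surround"`
#'   [CompartmentKinetics-class].
#' @param days numeric vector of days inside the kinetics support.
#' @param perCellNoiseCv lognormal coefficient of variation (>= 0).
#' @param nCells number of cells (>= 1).
#' @param seed integer seed.
#' @param phantom optional [NeuritePhantom-class] carried for provenance
#'   only; the table is purely analytic.
#' @return data.frame with columns `cell_id`, `day`, `compartment`
#'   (`bundle` | `surround` | `bin_edge_l` | `bin_int_l` | `bin_center` |
#'   `bin_int_r` | `bin_edge_r`), `intensity`.
#' @export
emitProfileTable <- function(kinetics, days, perCellNoiseCv = 0.10,
                             nCells = 30L, seed = 1L, phantom = NULL) {
  if (nCells < 1L) stop("nCells must be >= 1")
  if (perCellNoiseCv < 0) stop("perCellNoiseCv must be >= 0")
  kb <- pickKinetics(kinetics, "bundle")
  ks <- pickKinetics(kinetics, "surround")
  withBins <- length(kb@binLambda) > 0L || length(kb@spatialProfile) > 0L
  comps <- c("bundle", "surround", if (withBins) binNames)
  sdlog <- sqrt(log(1 + perCellNoiseCv^2))
  base <- do.call(rbind, lapply(days, function(d) {
    vals <- c(bundle = compartmentIntensity(kb, d),
              surround = compartmentIntensity(ks, d))
    if (withBins) vals <- c(vals, binIntensities(kb, d))
    data.frame(day = d, compartment = comps, intensity = as.numeric(vals))
  }))
  withSeed(seed, {
    res <- do.call(rbind, lapply(seq_len(nCells), function(i) {
      tab <- base
      if (perCellNoiseCv > 0)
        tab$intensity <- tab$intensity *
          stats::rlnorm(nrow(tab), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      cbind(cell_id = sprintf("cell_%03d", i), tab)
    }))
    rownames(res) <- NULL
    res
  })
}

#' Aggregate per-cell measurements into a per-day series
#'
#' Cells are first averaged over their segments/locations, then summarised
#' per day as cross-cell mean, standard error and count — the series shape
#' the decay fits consume.
#'
#' @param measurements data.frame from [measureCell()],
#'   [simulateCohort()] or [emitProfileTable()].
#' @param compartment compartment label to aggregate.
#' @param channel channel to keep (ignored when the table has no `channel`
#'   column).
#' @param segments optional subset of segment labels.
#' @return data.frame with columns `day`, `mean`, `sem`, `n` and attribute
#'   `compartment`.
#' @export
aggregateSeries <- function(measurements, compartment, channel = "gfp",
                            segments = NULL) {
  m <- measurements[measurements$compartment == compartment, , drop = FALSE]
  if ("channel" %in% names(m)) m <- m[m$channel == channel, , drop = FALSE]
  if (!is.null(segments) && "segment" %in% names(m))
    m <- m[m$segment %in% segments, , drop = FALSE]
  m <- m[!is.na(m$intensity), , drop = FALSE]
  if (!nrow(m)) stop("no records for compartment '", compartment, "'")
  percell <- stats::aggregate(intensity ~ cell_id + day, data = m, FUN = mean)
  agg <- do.call(rbind, lapply(split(percell, percell$day), function(g) {
    data.frame(day = g$day[1L], mean = mean(g$intensity),
               sem = stats::sd(g$intensity) / sqrt(nrow(g)), n = nrow(g))
  }))
  agg <- agg[order(agg$day), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "compartment") <- compartment
  agg
}

#' Per-cell bin-region series (center / interior / edge)
#'
#' Collapses the five raw bins to the three regions compared in decay
#' analyses: the center bin, the mean of the two interior bins and the mean
#' of the two edge bins, then aggregates per day.
#'
#' @inheritParams aggregateSeries
#' @param region `"center"`, `"interior"` or `"edge"`.
#' @return per-day aggregate data.frame (see [aggregateSeries()]).
#' @export
binRegionSeries <- function(measurements, region = c("center", "interior", "edge"),
                            channel = "gfp", segments = NULL) {
  region <- match.arg(region)
  comps <- switch(region,
    center = "bin_center",
    interior = c("bin_int_l", "bin_int_r"),
    edge = c("bin_edge_l", "bin_edge_r"))
  m <- measurements[measurements$compartment %in% comps, , drop = FALSE]
  if ("channel" %in% names(m)) m <- m[m$channel == channel, , drop = FALSE]
  if (!is.null(segments) && "segment" %in% names(m))
    m <- m[m$segment %in% segments, , drop = FALSE]
  m <- m[!is.na(m$intensity), , drop = FALSE]
  if (!nrow(m)) stop("no bin records found")
  m$compartment <- region
  aggregateSeries(m, region, channel = channel)
}
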