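# Lateral-profile quantification: transverse intensity profiles across a
# neurite, automatic bundle/surround separation, surround-corrected bundle
# values, five-bin binning and proximal/central/distal segmentation.

#' Extract a lateral (transverse) intensity profile
#'
#' Per transverse pixel, the mean intensity over a `2*halfwidth + 1`-column
#' longitudinal window centred at `locationPx`, for every channel. A window
#' crossing the image edge is trimmed with a warning.
#'
#' @param image a [NeuriteImage-class].
#' @param locationPx 0-based longitudinal location; must lie inside the
#'   image.
#' @param halfwidthPx longitudinal averaging half-width (default 2, i.e. a
#'   5-pixel window).
#' @return A [LateralProfile-class].
#' @export
extractLateralProfile <- function(image, locationPx, halfwidthPx = 2L) {
  W <- ncol(image@gfp)
  if (locationPx < 0L || locationPx >= W) stop("location outside image")
  lo <- locationPx - halfwidthPx
  hi <- locationPx + halfwidthPx
  if (lo < 0L || hi >= W) {
    warning("averaging window crosses the image edge; trimmed")
    lo <- max(lo, 0L)
    hi <- min(hi, W - 1L)
  }
  cols <- (lo:hi) + 1L
  inten <- cbind(
    gfp = rowMeans(image@gfp[, cols, drop = FALSE]),
    phospho = rowMeans(image@phospho[, cols, drop = FALSE]))
  new("LateralProfile", positionPx = seq_len(nrow(inten)) - 1L,
      intensity = inten, channelNames = colnames(inten),
      locationPx = as.integer(locationPx))
}

channelIndex <- function(profile, channel) {
  i <- match(channel, profile@channelNames)
  if (is.na(i)) stop("unknown channel: ", channel)
  i
}

# contiguous runs of TRUE as a (start, end) 1-based inclusive matrix
trueRuns <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect the transverse extent of the bundle
#'
#' Automatic replacement for a free-hand bundle selection: within the
#' neurite interval, the bundle is the contiguous run of pixels whose
#' reference-channel intensity exceeds `surround mean + k * surround SD`,
#' where the surround statistics come from the flanking within-neurite
#' regions (the outer quarter of the neurite interval on each side). When
#' several runs exceed the threshold, the run containing the neurite
#' midline is returned (the closest run if none contains it). The neurite
#' interval itself is the contiguous supra-background run containing the
#' intensity maximum, with background estimated from the profile tails.
#'
#' @param profile a [LateralProfile-class] covering the full neurite
#'   diameter plus background.
#' @param referenceChannel channel used for detection; defaults to the
#'   phospho-NF channel (stable across expression conditions), falling back
#'   to GFP when absent.
#' @param k threshold multiplier on the surround SD (default 2).
#' @return A [BundleExtent-class] (0-based half-open pixel intervals).
#' @export
detectBundleExtent <- function(profile, referenceChannel = "phospho", k = 2) {
  if (!referenceChannel %in% profile@channelNames)
    referenceChannel <- "gfp"
  v <- profile@intensity[, channelIndex(profile, referenceChannel)]
  n <- length(v)

  tails <- max(3L, floor(0.15 * n))
  bgVals <- c(v[seq_len(tails)], v[(n - tails + 1L):n])
  bgMean <- mean(bgVals)
  thrN <- bgMean + 2 * stats::sd(bgVals) + 1e-9 * max(1, abs(bgMean))
  above <- v > thrN
  if (!any(above)) stop("no bundle detected")
  runs <- trueRuns(above)
  peak <- which.max(v)
  hitN <- runs[runs[, 1L] <= peak & runs[, 2L] >= peak, , drop = FALSE]
  if (nrow(hitN) == 0L) stop("no bundle detected")
  ## second pass: re-threshold at a fixed fraction of the neurite contrast,
  ## so a single noisy background pixel cannot join the neurite interval
  level <- stats::median(v[hitN[1L, 1L]:hitN[1L, 2L]])
  thrN2 <- bgMean + 0.25 * (level - bgMean)
  runs <- trueRuns(v > thrN2)
  hitN <- runs[runs[, 1L] <= peak & runs[, 2L] >= peak, , drop = FALSE]
  if (nrow(hitN) == 0L) stop("no bundle detected")
  nStart <- hitN[1L, 1L]
  nEnd <- hitN[1L, 2L]
  L <- nEnd - nStart + 1L
  if (L < 5L) stop("no bundle detected")

  fl <- max(2L, floor(0.25 * L))
  flank <- c(v[nStart:(nStart + fl - 1L)], v[(nEnd - fl + 1L):nEnd])
  ## the k*SD rule, floored at a fraction of the bundle/surround contrast so
  ## that shot noise on a bright surround cannot admit surround pixels
  thr <- mean(flank) + max(k * stats::sd(flank),
                           0.25 * (max(v[nStart:nEnd]) - mean(flank)))
  inside <- seq.int(nStart, nEnd)
  cand <- v[inside] > thr
  if (!any(cand)) stop("no bundle detected")
  runs2 <- trueRuns(cand)
  mid <- (1L + L) %/% 2L
  hit <- runs2[runs2[, 1L] <= mid & runs2[, 2L] >= mid, , drop = FALSE]
  if (nrow(hit) == 0L) {
    d <- pmin(abs(runs2[, 1L] - mid), abs(runs2[, 2L] - mid))
    hit <- runs2[which.min(d), , drop = FALSE]
  }
  s1 <- inside[hit[1L, 1L]]
  e1 <- inside[hit[1L, 2L]]
  if (s1 <= nStart || e1 >= nEnd) stop("bundle/surround not separable")
  new("BundleExtent", startPx = s1 - 1L, endPx = e1,
      neuriteStartPx = nStart - 1L, neuriteEndPx = nEnd)
}

#' Surround-corrected bundle and surround values
#'
#' The neuritic cytoplasm on both sides of the bundle is averaged (mean of
#' the left-flank mean and the right-flank mean) and subtracted from the
#' bundle mean. Off-neurite background, estimated from pixels outside the
#' neurite interval, is subtracted from both quantities first (switch off
#' with `subtractBackground = FALSE`). A negative corrected bundle value is
#' kept as-is and flagged rather than clamped, so downstream decay fits are
#' not biased.
#'
#' @param profile a [LateralProfile-class].
#' @param extent a [BundleExtent-class] with at least one surround pixel on
#'   each side.
#' @param subtractBackground subtract the off-neurite background level.
#' @return data.frame with one row per channel: `channel`, `bundle`,
#'   `surround`, `background` (the subtracted off-neurite level),
#'   `negative` (flag).
#' @examples
#' ## bundle mean 1000, both flanks 400 -> bundle 600, surround 400
#' @export
surroundCorrectedBundle <- function(profile, extent, subtractBackground = TRUE) {
  ns <- extent@neuriteStartPx + 1L
  ne <- extent@neuriteEndPx
  bs <- extent@startPx + 1L
  be <- extent@endPx
  if (bs <= ns || be >= ne) stop("empty flank")
  out <- lapply(seq_along(profile@channelNames), function(ci) {
    v <- profile@intensity[, ci]
    bg <- 0
    if (subtractBackground) {
      off <- c(if (ns > 1L) v[seq_len(ns - 1L)],
               if (ne < length(v)) v[(ne + 1L):length(v)])
      if (length(off)) bg <- mean(off)
    }
    left <- v[ns:(bs - 1L)] - bg
    right <- v[(be + 1L):ne] - bg
    surround <- mean(c(mean(left), mean(right)))
    bundle <- mean(v[bs:be]) - bg - surround
    data.frame(channel = profile@channelNames[ci], bundle = bundle,
               surround = surround, background = bg, negative = bundle < 0)
  })
  do.call(rbind, out)
}

#' Five-bin transverse binning of the bundle
#'
#' Splits the bundle extent into five equal-width sub-intervals
#' (edge, interior, center, interior, edge). Pixels are treated as
#' unit-width intensity boxes; fractional bin boundaries split a pixel's
#' contribution proportionally (linear interpolation of the cumulative
#' profile), so the mean of the five raw bins equals the mean intensity
#' over the extent exactly, and a 5-pixel extent yields one pixel per bin.
#' With `normalize = TRUE` each bin is divided by the mean of the two edge
#' bins, giving a distribution profile comparable across neurites; raw
#' bins are required for decay-rate comparisons.
#'
#' @param profile a [LateralProfile-class].
#' @param extent a [BundleExtent-class] of width >= 5 pixels.
#' @param normalize divide bins by the edge-bin mean.
#' @param channel channel to bin (default `"gfp"`).
#' @return A [BinnedBundleProfile-class].
#' @export
binBundle <- function(profile, extent, normalize = FALSE, channel = "gfp") {
  w <- extent@endPx - extent@startPx
  if (w < 5L) stop("bundle too narrow to bin")
  v <- profile@intensity[(extent@startPx + 1L):extent@endPx,
                         channelIndex(profile, channel)]
  cum <- c(0, cumsum(v))
  intAt <- function(x) {        # integral of the piecewise-constant profile over [0, x]
    i <- floor(x)
    frac <- x - i
    cum[i + 1L] + ifelse(i < w, frac * v[pmin(i + 1L, w)], 0)
  }
  bounds <- seq(0, w, length.out = 6L)
  bins <- (intAt(bounds[-1L]) - intAt(bounds[-6L])) / (w / 5)
  names(bins) <- binNames
  edgeMean <- mean(bins[c(1L, 5L)])
  if (normalize) {
    if (edgeMean <= 0) stop("edge-bin mean not positive; cannot normalize")
    bins <- bins / edgeMean
  }
  new("BinnedBundleProfile", bins = bins, normalized = isTRUE(normalize),
      edgeMean = edgeMean)
}

#' Partition a neurite axis into proximal, central and distal segments
#'
#' After excluding the hillock and growth cone, the remaining length is
#' split into three contiguous half-open intervals of equal length; the
#' remainder (`length mod 3`) is assigned to the distal segment.
#'
#' @param neuriteAxisLengthPx total axis length in pixels.
#' @param hillockPx,growthconePx exclusions at either end.
#' @return A [SegmentPartition-class].
#' @examples
#' partitionSegments(300, 0, 0)     # [0,100) [100,200) [200,300)
#' partitionSegments(310, 5, 5)     # three 100-px segments over [5,305)
#' @export
partitionSegments <- function(neuriteAxisLengthPx, hillockPx = 0L,
                              growthconePx = 0L) {
  lo <- as.integer(hillockPx)
  hi <- as.integer(neuriteAxisLengthPx - growthconePx)
  len <- hi - lo
  if (len < 3L) stop("analyzable length < 3")
  base <- len %/% 3L
  b <- matrix(c(lo, lo + base,
                lo + base, lo + 2L * base,
                lo + 2L * base, hi), nrow = 3L, byrow = TRUE,
              dimnames = list(c("proximal", "central", "distal"),
                              c("start", "end")))
  new("SegmentPartition", bounds = b)
}
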