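# Rendering of synthetic neurite images: axis-aligned neurite (horizontal,
# bundle centred on the axis row), per-compartment decay kinetics, optional
# photobleach, Poisson + Gaussian camera noise with per-column substreams so
# that bleaching a region never perturbs pixels outside it.

pickKinetics <- function(kinetics, compartment) {
  hit <- Filter(function(k) k@compartment == compartment, kinetics)
  if (length(hit) != 1L)
    stop("kinetics must contain exactly one 'bundle' and one 'surround' entry")
  hit[[1L]]
}

# label mask and per-column neurite spans for a phantom
buildGeometry <- function(phantom) {
  H <- phantom@imageHeightPx
  W <- phantom@lengthPx
  extra <- varicosityExtra(phantom, seq_len(W) - 1)
  spans <- vapply(extra, function(e) neuriteRowSpan(phantom, e), integer(2))
  spans[1L, ] <- pmax(spans[1L, ], 1L)
  spans[2L, ] <- pmin(spans[2L, ], H)
  bspan <- bundleRowSpan(phantom)
  mask <- matrix(0L, H, W)
  for (j in seq_len(W)) mask[spans[1L, j]:spans[2L, j], j] <- 1L
  mask[bspan[1L]:bspan[2L], ] <- 2L
  list(mask = mask, spans = spans, bundleSpan = bspan)
}

gaussianBlurColumns <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  half <- max(1L, ceiling(3 * sigma))
  x <- (-half):half
  kern <- exp(-x^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  n <- nrow(mat)
  pad <- rbind(mat[rep(1L, half), , drop = FALSE], mat,
               mat[rep(n, half), , drop = FALSE])
  out <- apply(pad, 2L, function(col) stats::filter(col, kern, sides = 2L))
  out[(half + 1L):(half + n), , drop = FALSE]
}

#' Render one synthetic neurite frame
#'
#' Paints a two-channel, 16-bit-range image of a horizontal neurite: the
#' GFP channel follows the supplied compartment kinetics at `day` (the
#' surround filling the neurite, the five-bin bundle signal centred on the
#' axis row), the phospho-NF stand-in channel is constant over days and
#' highlights the bundle. Without noise and blur, the mean intensity of
#' each labelled compartment equals the analytic trajectory at `day`
#' (plus the background level); with `additive` bundle kinetics the bundle
#' pixels carry surround plus bundle signal, so that the surround-corrected
#' bundle measurement recovers the bundle trajectory.
#'
#' @param phantom a [NeuritePhantom-class].
#' @param kinetics list with exactly one `"bundle"` and one `"surround"`
#'   [CompartmentKinetics-class].
#' @param day day in culture; must fall inside every kinetics phase range.
#' @param config an [AcquisitionConfig-class]; noise and quantization are
#'   applied only when enabled there.
#' @param bleach optional [BleachSpec-class] applied inside its region for
#'   days at or after the bleach day.
#' @param intensityScale named numeric, multiplicative factors
#'   `c(bundle = , surround = )` applied to the trajectories (used by
#'   [simulateCohort()] for per-cell variation).
#' @param frameIndex integer used to derive per-frame noise substreams.
#' @return A [NeuriteImage-class] (channels plus ground-truth label mask).
#' @examples
#' ph <- NeuritePhantom(backgroundLevel = 0)
#' kin <- list(
#'   CompartmentKinetics("bundle", 1000, c(0, 4, 0)),
#'   CompartmentKinetics("surround", 400, c(0, 4, 0)))
#' img <- renderNeuriteImage(ph, kin, day = 2,
#'   config = AcquisitionConfig(gaussianReadNoiseSd = 0, poissonNoise = FALSE))
#' mean(gfpChannel(img)[labelMask(img) == 2L])  # 1000
#' @export
renderNeuriteImage <- function(phantom, kinetics, day,
                               config = AcquisitionConfig(), bleach = NULL,
                               intensityScale = c(bundle = 1, surround = 1),
                               frameIndex = 0L) {
  stopifnot(is(phantom, "NeuritePhantom"))
  kb <- pickKinetics(kinetics, "bundle")
  ks <- pickKinetics(kinetics, "surround")
  H <- phantom@imageHeightPx
  W <- phantom@lengthPx
  geo <- buildGeometry(phantom)
  bg <- phantom@backgroundLevel

  sOut <- compartmentIntensity(ks, day) * intensityScale[["surround"]]
  bOutBins <- binIntensities(kb, day) * intensityScale[["bundle"]]
  if (!is.null(bleach)) {
    sIn <- compartmentIntensity(ks, day, bleach = bleach) * intensityScale[["surround"]]
    bInBins <- binIntensities(kb, day, bleach = bleach) * intensityScale[["bundle"]]
  }

  w <- phantom@bundleWidthPx
  rw <- binRowWeights(w)
  bRowsOut <- as.vector(rw %*% bOutBins)
  if (!is.null(bleach)) bRowsIn <- as.vector(rw %*% bInBins)
  bspan <- geo$bundleSpan

  gfp <- matrix(bg, H, W)
  phospho <- matrix(bg, H, W)
  inRegion <- if (is.null(bleach)) rep(FALSE, W) else
    (seq_len(W) - 1L) >= bleach@regionStartPx & (seq_len(W) - 1L) < bleach@regionEndPx
  for (j in seq_len(W)) {
    rows <- geo$spans[1L, j]:geo$spans[2L, j]
    sv <- if (inRegion[j]) sIn else sOut
    bv <- if (inRegion[j]) bRowsIn else bRowsOut
    gfp[rows, j] <- bg + sv
    brows <- bspan[1L]:bspan[2L]
    gfp[brows, j] <- if (kb@additive) bg + sv + bv else bg + bv
    phospho[rows, j] <- bg + phantom@phosphoSurroundLevel
    phospho[brows, j] <- bg + phantom@phosphoSurroundLevel + phantom@phosphoBundleLevel
  }

  if (config@psfSigmaPx > 0) {
    gfp <- gaussianBlurColumns(gfp, config@psfSigmaPx)
    phospho <- gaussianBlurColumns(phospho, config@psfSigmaPx)
  }

  maxVal <- 2^config@pixelBitDepth - 1
  noisy <- config@poissonNoise || config@gaussianReadNoiseSd > 0
  if (noisy) {
    sd <- config@gaussianReadNoiseSd
    for (j in seq_len(W)) {
      withSeed(subSeed(config@seed, as.double(frameIndex) * 100003 + j), {
        g <- gfp[, j]
        p <- phospho[, j]
        if (config@poissonNoise) {
          g <- stats::rpois(H, pmax(g, 0))
          p <- stats::rpois(H, pmax(p, 0))
        }
        if (sd > 0) {
          g <- g + stats::rnorm(H, 0, sd)
          p <- p + stats::rnorm(H, 0, sd)
        }
        gfp[, j] <- g
        phospho[, j] <- p
      })
    }
    gfp <- pmin(pmax(round(gfp), 0), maxVal)
    phospho <- pmin(pmax(round(phospho), 0), maxVal)
  } else {
    gfp <- pmin(pmax(gfp, 0), maxVal)
    phospho <- pmin(pmax(phospho, 0), maxVal)
  }

  new("NeuriteImage", gfp = gfp, phospho = phospho, mask = geo$mask,
      day = day, phantom = phantom, noisy = noisy)
}

#' Render a day series of synthetic frames
#'
#' One frame per day with consistent geometry; noise substreams are derived
#' from the acquisition seed and the frame index, so a series is
#' reproducible frame by frame and a single-day series is identical to
#' [renderNeuriteImage()].
#'
#' @inheritParams renderNeuriteImage
#' @param days strictly increasing, non-empty numeric vector of days.
#' @param intensityScale `NULL`, or a `2 x length(days)` matrix with rows
#'   `bundle`, `surround` of per-frame multiplicative factors.
#' @return A [NeuriteStack-class].
#' @export
renderTimeSeries <- function(phantom, kinetics, days,
                             config = AcquisitionConfig(), bleach = NULL,
                             intensityScale = NULL) {
  if (length(days) == 0L) stop("days must be non-empty")
  if (is.unsorted(days, strictly = TRUE)) stop("days must be strictly increasing")
  if (is.null(intensityScale))
    intensityScale <- matrix(1, nrow = 2L, ncol = length(days),
                             dimnames = list(c("bundle", "surround"), NULL))
  frames <- lapply(seq_along(days), function(i) {
    renderNeuriteImage(phantom, kinetics, days[i], config = config,
      bleach = bleach,
      intensityScale = c(bundle = unname(intensityScale["bundle", i]),
                         surround = unname(intensityScale["surround", i])),
      frameIndex = i - 1L)
  })
  new("NeuriteStack", frames = frames, days = as.numeric(days),
      phantom = phantom, kinetics = kinetics, config = config,
      bleach = bleach, intensityScale = intensityScale)
}

#' Apply a photobleach event to a rendered series
#'
#' Re-evaluates every frame with the bleach model active: inside the
#' bleached region, from the bleach day on, intensities follow the bleach
#' trajectory (destruction then end-point recovery); pixels outside the
#' region are unchanged at every time point (noise substreams are drawn per
#' image column).
#'
#' @param stack a [NeuriteStack-class].
#' @param bleach a [BleachSpec-class]; its region must lie within the
#'   neurite length and its day within the series' time support.
#' @return A new [NeuriteStack-class].
#' @export
applyBleach <- function(stack, bleach) {
  stopifnot(is(stack, "NeuriteStack"), is(bleach, "BleachSpec"))
  if (bleach@regionStartPx < 0L || bleach@regionEndPx > stack@phantom@lengthPx)
    stop("bleach region outside neurite length")
  if (bleach@bleachDay < min(stack@days) || bleach@bleachDay > max(stack@days))
    stop("bleach day outside the series' time support")
  renderTimeSeries(stack@phantom, stack@kinetics, stack@days,
                   config = stack@config, bleach = bleach,
                   intensityScale = stack@intensityScale)
}
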