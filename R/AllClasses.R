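#' @import methods
NULL

#' Ground-truth geometry of a synthetic neurite
#'
#' A `NeuritePhantom` holds the morphology of one synthetic axonal neurite:
#' a horizontal neurite of given length and diameter containing a
#' centrally-situated longitudinal neurofilament bundle, optional
#' varicosities (local swellings that widen the surround), and margins at
#' either end (hillock, growth cone) that are excluded from analysis.
#' All pixel coordinates are 0-based; intervals are half-open.
#'
#' @slot lengthPx neurite length in pixels (image width), >= 50.
#' @slot diameterPx neurite diameter in pixels, >= 9.
#' @slot bundleWidthPx transverse width of the bundle, >= 5 and strictly
#'   less than `diameterPx` so that a surround exists on both sides.
#' @slot axisRow image row (0-based) of the neurite midline.
#' @slot imageHeightPx total image height in pixels.
#' @slot varicosities two-column matrix (`positionPx`, `extraDiameterPx`);
#'   positions must lie within the analyzable region.
#' @slot backgroundLevel camera background added to every pixel (a.u.).
#' @slot hillockPx,growthconePx lengths excluded from analysis at the
#'   proximal and distal ends.
#' @slot phosphoBundleLevel,phosphoSurroundLevel intensities of the
#'   phospho-neurofilament immunostain channel (a.u.); constant over days
#'   in culture, the bundle level painted on top of the surround level.
#' @seealso [NeuritePhantom()]
#' @exportClass NeuritePhantom
setClass("NeuritePhantom",
  slots = c(
    lengthPx = "integer",
    diameterPx = "integer",
    bundleWidthPx = "integer",
    axisRow = "integer",
    imageHeightPx = "integer",
    varicosities = "matrix",
    backgroundLevel = "numeric",
    hillockPx = "integer",
    growthconePx = "integer",
    phosphoBundleLevel = "numeric",
    phosphoSurroundLevel = "numeric"
  )
)

setValidity("NeuritePhantom", function(object) {
  msg <- character()
  if (object@lengthPx < 50L) msg <- c(msg, "lengthPx must be >= 50")
  if (object@diameterPx < 9L) msg <- c(msg, "diameterPx must be >= 9")
  if (object@bundleWidthPx < 5L) msg <- c(msg, "bundleWidthPx must be >= 5")
  if (object@bundleWidthPx >= object@diameterPx)
    msg <- c(msg, "bundleWidthPx must be < diameterPx (a surround must exist on both sides)")
  if (object@hillockPx < 0L || object@growthconePx < 0L)
    msg <- c(msg, "hillockPx and growthconePx must be non-negative")
  if (object@backgroundLevel < 0) msg <- c(msg, "backgroundLevel must be non-negative")
  if (ncol(object@varicosities) != 2L)
    msg <- c(msg, "varicosities must have two columns (positionPx, extraDiameterPx)")
  if (nrow(object@varicosities) > 0L) {
    pos <- object@varicosities[, 1L]
    lo <- object@hillockPx
    hi <- object@lengthPx - object@growthconePx
    if (any(pos < lo | pos >= hi))
      msg <- c(msg, "all varicosity positions must lie within [hillockPx, lengthPx - growthconePx)")
  }
  extra <- if (nrow(object@varicosities)) max(object@varicosities[, 2L]) else 0
  if (object@imageHeightPx < object@diameterPx + extra + 4)
    msg <- c(msg, "imageHeightPx too small for neurite plus varicosities")
  span <- neuriteRowSpan(object)
  if (span[1L] < 1L || span[2L] > object@imageHeightPx)
    msg <- c(msg, "neurite does not fit in the image at axisRow")
  if (length(msg)) msg else TRUE
})

#' Construct a synthetic-neurite phantom
#'
#' @param lengthPx,diameterPx,bundleWidthPx neurite geometry in pixels.
#' @param varicosities `NULL`, or a two-column matrix / data.frame of
#'   (`positionPx`, `extraDiameterPx`) local swellings.
#' @param backgroundLevel camera background (a.u.) added to every pixel.
#' @param hillockPx,growthconePx margins excluded from analysis.
#' @param axisRow 0-based image row of the midline; defaults to the image
#'   center.
#' @param imageHeightPx image height; defaults to the diameter plus a margin
#'   accommodating the widest varicosity.
#' @param phosphoBundleLevel,phosphoSurroundLevel intensities of the
#'   phospho-NF stand-in channel (a.u.).
#' @return A [NeuritePhantom-class] object.
#' @examples
#' ph <- NeuritePhantom(lengthPx = 220L, diameterPx = 15L, bundleWidthPx = 5L)
#' ph
#' @export
NeuritePhantom <- function(lengthPx = 220L, diameterPx = 15L,
                           bundleWidthPx = 5L, varicosities = NULL,
                           backgroundLevel = 0, hillockPx = 10L,
                           growthconePx = 10L, axisRow = NULL,
                           imageHeightPx = NULL,
                           phosphoBundleLevel = 1200,
                           phosphoSurroundLevel = 300) {
  if (is.null(varicosities)) {
    varicosities <- matrix(numeric(0), nrow = 0L, ncol = 2L)
  } else {
    varicosities <- as.matrix(varicosities)
  }
  colnames(varicosities) <- c("positionPx", "extraDiameterPx")
  extra <- if (nrow(varicosities)) max(varicosities[, 2L]) else 0
  if (is.null(imageHeightPx))
    imageHeightPx <- as.integer(diameterPx + ceiling(extra) + 16L)
  if (is.null(axisRow)) axisRow <- as.integer(imageHeightPx %/% 2L)
  new("NeuritePhantom",
    lengthPx = as.integer(lengthPx), diameterPx = as.integer(diameterPx),
    bundleWidthPx = as.integer(bundleWidthPx), axisRow = as.integer(axisRow),
    imageHeightPx = as.integer(imageHeightPx), varicosities = varicosities,
    backgroundLevel = as.numeric(backgroundLevel),
    hillockPx = as.integer(hillockPx), growthconePx = as.integer(growthconePx),
    phosphoBundleLevel = as.numeric(phosphoBundleLevel),
    phosphoSurroundLevel = as.numeric(phosphoSurroundLevel))
}

#' Per-compartment decay kinetics
#'
#' Intensity of one compartment (bundle or surround) over days in culture,
#' modelled as piecewise mono-exponential decay
#' `N(t) = N0 * exp(-lambda * (t - t0))` within each phase, continuous at
#' phase boundaries (the value reached at a breakpoint seeds the next
#' phase). `lambda >= 0` and the half-life is `ln(2)/lambda`.
#'
#' For the bundle, optional five-bin structure describes the transverse
#' distribution: `spatialProfile` multiplies `N0` per bin
#' (edge/interior/center/interior/edge) and `binLambda` gives each bin its
#' own decay coefficient (per day, from the start of the first phase).
#' When `additive = TRUE` the bundle values are painted on top of the
#' surround signal (bundled fluorophore superimposed on the cytoplasm that
#' overlies the bundle), so that the surround-corrected bundle measurement
#' recovers this trajectory directly.
#'
#' @slot compartment `"bundle"` or `"surround"`.
#' @slot N0 intensity (a.u.) at the start of the first phase.
#' @slot phases matrix with columns `startDay`, `endDay`, `lambdaPerDay`;
#'   phases contiguous, non-overlapping, `lambdaPerDay >= 0`.
#' @slot spatialProfile numeric(0) or numeric(5) per-bin multipliers.
#' @slot binLambda numeric(0) or numeric(5) per-bin decay coefficients.
#' @slot additive logical; bundle painted additively over the surround.
#' @seealso [CompartmentKinetics()]
#' @exportClass CompartmentKinetics
setClass("CompartmentKinetics",
  slots = c(
    compartment = "character",
    N0 = "numeric",
    phases = "matrix",
    spatialProfile = "numeric",
    binLambda = "numeric",
    additive = "logical"
  )
)

setValidity("CompartmentKinetics", function(object) {
  msg <- character()
  if (!object@compartment %in% c("bundle", "surround"))
    msg <- c(msg, "compartment must be 'bundle' or 'surround'")
  if (object@N0 < 0) msg <- c(msg, "N0 must be non-negative")
  ph <- object@phases
  if (ncol(ph) != 3L || nrow(ph) < 1L) {
    msg <- c(msg, "phases must be a matrix with columns startDay, endDay, lambdaPerDay")
  } else {
    if (any(ph[, 2L] <= ph[, 1L])) msg <- c(msg, "each phase must have endDay > startDay")
    if (any(ph[, 3L] < 0)) msg <- c(msg, "lambdaPerDay must be >= 0")
    if (nrow(ph) > 1L && any(abs(ph[-1L, 1L] - ph[-nrow(ph), 2L]) > 1e-9))
      msg <- c(msg, "phases must be contiguous and non-overlapping in time")
  }
  if (!length(object@spatialProfile) %in% c(0L, 5L))
    msg <- c(msg, "spatialProfile must have length 5 (or be absent)")
  if (!length(object@binLambda) %in% c(0L, 5L))
    msg <- c(msg, "binLambda must have length 5 (or be absent)")
  if (length(object@binLambda) && any(object@binLambda < 0))
    msg <- c(msg, "binLambda must be >= 0")
  if (length(object@spatialProfile) && any(object@spatialProfile < 0))
    msg <- c(msg, "spatialProfile must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct compartment kinetics
#'
#' @param compartment `"bundle"` or `"surround"`.
#' @param N0 intensity (a.u.) at the reference day (start of first phase).
#' @param phases matrix or data.frame with columns `startDay`, `endDay`,
#'   `lambdaPerDay`. A single phase can be given as `c(start, end, lambda)`.
#' @param spatialProfile optional numeric(5) per-bin multipliers of `N0`
#'   (order edge, interior, center, interior, edge).
#' @param binLambda optional numeric(5) per-bin decay coefficients per day.
#' @param additive paint bundle values on top of the surround signal
#'   (see [CompartmentKinetics-class]).
#' @return A [CompartmentKinetics-class] object.
#' @examples
#' ## surround with a fast early phase and a slow late phase
#' CompartmentKinetics("surround", N0 = 1000, phases = rbind(
#'   c(2, 4, log(2) / 0.9),
#'   c(4, 14, log(2) / 5.7)))
#' @export
CompartmentKinetics <- function(compartment, N0, phases,
                                spatialProfile = NULL, binLambda = NULL,
                                additive = FALSE) {
  if (is.null(dim(phases))) phases <- matrix(phases, nrow = 1L)
  phases <- as.matrix(phases)
  colnames(phases) <- c("startDay", "endDay", "lambdaPerDay")
  new("CompartmentKinetics",
    compartment = compartment, N0 = as.numeric(N0), phases = phases,
    spatialProfile = if (is.null(spatialProfile)) numeric(0) else as.numeric(spatialProfile),
    binLambda = if (is.null(binLambda)) numeric(0) else as.numeric(binLambda),
    additive = isTRUE(additive))
}

#' Acquisition (camera) settings for synthetic images
#'
#' Standard fluorescence-camera noise model: Poisson shot noise on the
#' expected signal plus additive Gaussian read noise, optional transverse
#' Gaussian blur, 16-bit quantization with clipping to `[0, 2^16 - 1]`.
#' All randomness is derived deterministically from `seed` (per frame and
#' per image column), so identical inputs give bit-identical images.
#'
#' @slot pixelBitDepth always 16.
#' @slot gaussianReadNoiseSd read-noise standard deviation (a.u.).
#' @slot poissonNoise enable shot noise.
#' @slot psfSigmaPx transverse Gaussian blur sigma in pixels (0 = none).
#' @slot seed integer seed.
#' @exportClass AcquisitionConfig
setClass("AcquisitionConfig",
  slots = c(
    pixelBitDepth = "integer",
    gaussianReadNoiseSd = "numeric",
    poissonNoise = "logical",
    psfSigmaPx = "numeric",
    seed = "integer"
  )
)

setValidity("AcquisitionConfig", function(object) {
  msg <- character()
  if (object@pixelBitDepth != 16L) msg <- c(msg, "pixelBitDepth must be 16")
  if (object@gaussianReadNoiseSd < 0) msg <- c(msg, "gaussianReadNoiseSd must be >= 0")
  if (object@psfSigmaPx < 0) msg <- c(msg, "psfSigmaPx must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname AcquisitionConfig-class
#' @param gaussianReadNoiseSd,poissonNoise,psfSigmaPx,seed see slots.
#' @return An [AcquisitionConfig-class] object.
#' @export
AcquisitionConfig <- function(gaussianReadNoiseSd = 10, poissonNoise = TRUE,
                              psfSigmaPx = 0, seed = 1L) {
  new("AcquisitionConfig", pixelBitDepth = 16L,
    gaussianReadNoiseSd = as.numeric(gaussianReadNoiseSd),
    poissonNoise = isTRUE(poissonNoise), psfSigmaPx = as.numeric(psfSigmaPx),
    seed = as.integer(seed))
}

#' Photobleach event specification
#'
#' A single bleach of a longitudinal neurite region at `bleachDay`,
#' destroying `efficiency` of the fluorescence inside the region in both
#' compartments, followed by an end-point recovery `recoveryDelayDays`
#' later. Recovery is modelled per compartment as
#' `post = pre * ((1 - efficiency) + recoveryFraction * efficiency)`
#' where `pre` is the value at the moment of bleaching: a recovery fraction
#' of 1 restores the pre-bleach level, 0 leaves the bleached level. The
#' default fractions encode the observed behaviour — the surround refills
#' to above 90% of its pre-bleach level within 10-12 h while the bundle
#' remains at its bleached level.
#'
#' @slot regionStartPx,regionEndPx longitudinal interval (0-based,
#'   half-open) that was exposed to the beam.
#' @slot bleachDay day in culture of the bleach.
#' @slot efficiency fraction of fluorescence destroyed, in `[0, 1]`.
#' @slot surroundRecoveryFraction,bundleRecoveryFraction fraction of the
#'   destroyed signal replaced by the recovery end-point, in `[0, 1]`.
#' @slot recoveryDelayDays delay of the recovery end-point (days).
#' @exportClass BleachSpec
setClass("BleachSpec",
  slots = c(
    regionStartPx = "integer",
    regionEndPx = "integer",
    bleachDay = "numeric",
    efficiency = "numeric",
    surroundRecoveryFraction = "numeric",
    bundleRecoveryFraction = "numeric",
    recoveryDelayDays = "numeric"
  )
)

setClassUnion("BleachSpecOrNULL", c("BleachSpec", "NULL"))

setValidity("BleachSpec", function(object) {
  msg <- character()
  if (object@regionEndPx <= object@regionStartPx)
    msg <- c(msg, "bleach region must be a non-empty half-open interval")
  if (object@efficiency < 0 || object@efficiency > 1)
    msg <- c(msg, "efficiency must be in [0, 1]")
  fr <- c(object@surroundRecoveryFraction, object@bundleRecoveryFraction)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "recovery fractions must be in [0, 1]")
  if (object@recoveryDelayDays <= 0) msg <- c(msg, "recoveryDelayDays must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname BleachSpec-class
#' @param regionStartPx,regionEndPx,bleachDay,efficiency see slots.
#' @param surroundRecoveryFraction,bundleRecoveryFraction,recoveryDelayDays
#'   see slots.
#' @return A [BleachSpec-class] object.
#' @export
BleachSpec <- function(regionStartPx, regionEndPx, bleachDay,
                       efficiency = 0.95, surroundRecoveryFraction = 0.92,
                       bundleRecoveryFraction = 0, recoveryDelayDays = 0.5) {
  new("BleachSpec", regionStartPx = as.integer(regionStartPx),
    regionEndPx = as.integer(regionEndPx), bleachDay = as.numeric(bleachDay),
    efficiency = as.numeric(efficiency),
    surroundRecoveryFraction = as.numeric(surroundRecoveryFraction),
    bundleRecoveryFraction = as.numeric(bundleRecoveryFraction),
    recoveryDelayDays = as.numeric(recoveryDelayDays))
}

#' A rendered two-channel synthetic neurite image
#'
#' Channel 1 (`gfp`) carries the GFP signal following the compartment
#' kinetics; channel 2 (`phospho`) is the phospho-neurofilament immunostain
#' stand-in, constant over days and highlighting the bundle. `mask` labels
#' pixels 0 = background, 1 = surround, 2 = bundle.
#'
#' @slot gfp,phospho,mask matrices of dimension `imageHeightPx x lengthPx`.
#' @slot day day in culture the frame represents.
#' @slot phantom the generating [NeuritePhantom-class].
#' @slot noisy whether acquisition noise/quantization was applied.
#' @exportClass NeuriteImage
setClass("NeuriteImage",
  slots = c(gfp = "matrix", phospho = "matrix", mask = "matrix",
            day = "numeric", phantom = "NeuritePhantom", noisy = "logical"))

#' A day-indexed stack of synthetic neurite frames
#'
#' @slot frames list of [NeuriteImage-class] objects, one per day.
#' @slot days strictly increasing days in culture.
#' @slot phantom,kinetics,config,bleach the generating parameters
#'   (`bleach` may be `NULL`).
#' @exportClass NeuriteStack
setClass("NeuriteStack",
  slots = c(frames = "list", days = "numeric", phantom = "NeuritePhantom",
            kinetics = "list", config = "AcquisitionConfig",
            bleach = "BleachSpecOrNULL", intensityScale = "matrix"))

#' A transverse intensity profile across a neurite
#'
#' Per-channel intensity as a function of transverse (row) position at a
#' fixed longitudinal location, averaged over a short longitudinal window.
#'
#' @slot positionPx 0-based transverse pixel offsets, strictly increasing.
#' @slot intensity matrix, one column per channel.
#' @slot channelNames column names of `intensity`.
#' @slot locationPx 0-based longitudinal location of the profile.
#' @exportClass LateralProfile
setClass("LateralProfile",
  slots = c(positionPx = "integer", intensity = "matrix",
            channelNames = "character", locationPx = "integer"))

setValidity("LateralProfile", function(object) {
  msg <- character()
  if (is.unsorted(object@positionPx, strictly = TRUE))
    msg <- c(msg, "positionPx must be strictly increasing")
  if (nrow(object@intensity) != length(object@positionPx))
    msg <- c(msg, "intensity must have one row per position")
  if (ncol(object@intensity) != length(object@channelNames))
    msg <- c(msg, "one channel name per intensity column")
  if (length(msg)) msg else TRUE
})

#' Transverse extent of the bundle within a profile
#'
#' Half-open, 0-based interval `[startPx, endPx)` of bundle pixels within a
#' [LateralProfile-class], strictly interior to the detected neurite
#' interval `[neuriteStartPx, neuriteEndPx)` so that surround flanks exist
#' on both sides.
#'
#' @slot startPx,endPx bundle interval.
#' @slot neuriteStartPx,neuriteEndPx neurite interval.
#' @exportClass BundleExtent
setClass("BundleExtent",
  slots = c(startPx = "integer", endPx = "integer",
            neuriteStartPx = "integer", neuriteEndPx = "integer"))

setValidity("BundleExtent", function(object) {
  msg <- character()
  if (object@endPx <= object@startPx) msg <- c(msg, "extent must be non-empty")
  if (object@startPx <= object@neuriteStartPx || object@endPx >= object@neuriteEndPx)
    msg <- c(msg, "extent must be strictly interior to the neurite interval")
  if (length(msg)) msg else TRUE
})

#' Five-bin transverse summary of a bundle profile
#'
#' The bundle extent split into five equal-width transverse bins
#' (edge, interior, center, interior, edge); optionally each bin divided by
#' the mean of the two edge bins so profiles from different neurites can be
#' pooled.
#'
#' @slot bins named numeric(5) in order edge_l, interior_l, center,
#'   interior_r, edge_r.
#' @slot normalized whether bins were divided by the edge mean.
#' @slot edgeMean the divisor used when `normalized` (otherwise the raw
#'   edge mean).
#' @exportClass BinnedBundleProfile
setClass("BinnedBundleProfile",
  slots = c(bins = "numeric", normalized = "logical", edgeMean = "numeric"))

setValidity("BinnedBundleProfile", function(object) {
  msg <- character()
  if (length(object@bins) != 5L) msg <- c(msg, "exactly five bins required")
  if (object@normalized && abs(mean(object@bins[c(1L, 5L)]) - 1) > 1e-9)
    msg <- c(msg, "normalized profile must have edge-bin mean 1")
  if (length(msg)) msg else TRUE
})

#' Proximal/central/distal segmentation of a neurite
#'
#' The analyzable neurite length (hillock and growth cone excluded) split
#' into three contiguous half-open intervals of equal length; remainder
#' pixels are assigned to the distal segment.
#'
#' @slot bounds 3 x 2 matrix of (start, end), rows proximal/central/distal.
#' @exportClass SegmentPartition
setClass("SegmentPartition", slots = c(bounds = "matrix"))

setValidity("SegmentPartition", function(object) {
  b <- object@bounds
  msg <- character()
  if (!identical(dim(b), c(3L, 2L))) msg <- c(msg, "bounds must be 3 x 2")
  else {
    if (any(b[, 2L] <= b[, 1L])) msg <- c(msg, "segments must be non-empty")
    if (any(b[-1L, 1L] != b[-3L, 2L])) msg <- c(msg, "segments must be contiguous")
    len <- b[, 2L] - b[, 1L]
    if (max(len) - min(len) > ceiling(max(len) %% 3 + 2))
      msg <- c(msg, "segment lengths must be equal within the remainder rule")
  }
  if (length(msg)) msg else TRUE
})

#' A fitted mono-exponential decay
#'
#' Result of an ordinary least-squares fit of `log(intensity)` on
#' `day - t0`: intensity is modelled as `N(t) = N0 * exp(-lambda (t - t0))`
#' with half-life `ln(2)/lambda`. A non-positive fitted `lambda` is kept
#' (sign retained) but flagged `"no decay"` with infinite half-life.
#'
#' @slot n0 fitted intensity at `t0` (a.u.).
#' @slot lambda fitted decay coefficient per day.
#' @slot halfLifeDays `ln(2)/lambda` (Inf when `lambda <= 0`).
#' @slot t0 reference day (first day of the fit window).
#' @slot rSquared r-squared of the log-linear fit.
#' @slot window `(firstDay, lastDay)` of the data used.
#' @slot flag `"ok"` or `"no decay"`.
#' @exportClass DecayFit
setClass("DecayFit",
  slots = c(n0 = "numeric", lambda = "numeric", halfLifeDays = "numeric",
            t0 = "numeric", rSquared = "numeric", window = "numeric",
            flag = "character"))

#' A bi-phasic decay fit
#'
#' Two independent mono-exponential fits split at `breakpointDay`; the
#' breakpoint observation is shared by both windows.
#'
#' @slot early,late [DecayFit-class] objects for the two phases.
#' @slot breakpointDay the fixed breakpoint (day).
#' @exportClass BiphasicFit
setClass("BiphasicFit",
  slots = c(early = "DecayFit", late = "DecayFit", breakpointDay = "numeric"))

#' Photobleach-recovery quantification
#'
#' @slot pre,postBleach,recovered intensities before, immediately after,
#'   and 10-12 h after photobleaching (a.u.).
#' @slot fractionOfPre `recovered / pre`.
#' @slot fractionOfLost `(recovered - postBleach) / (pre - postBleach)`
#'   (NA when no signal was lost).
#' @slot flag `"ok"` or `"no bleach detected"` (post above pre).
#' @exportClass RecoveryResult
setClass("RecoveryResult",
  slots = c(pre = "numeric", postBleach = "numeric", recovered = "numeric",
            fractionOfPre = "numeric", fractionOfLost = "numeric",
            flag = "character"))

#' A two-condition comparison
#'
#' Unpaired two-tailed Student's t-test with pooled variance, plus the fold
#' difference of group means.
#'
#' @slot metric name of the compared quantity.
#' @slot labels condition labels (length 2).
#' @slot means,sds,ns per-condition mean, SD and n.
#' @slot foldDifference `means[1] / means[2]`.
#' @slot tStatistic,pValue the test.
#' @exportClass ConditionComparison
setClass("ConditionComparison",
  slots = c(metric = "character", labels = "character", means = "numeric",
            sds = "numeric", ns = "numeric", foldDifference = "numeric",
            tStatistic = "numeric", pValue = "numeric"))
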