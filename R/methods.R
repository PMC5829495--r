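# Accessors and show methods.

#' @describeIn NeuriteImage-class GFP channel matrix.
#' @param x,object a [NeuriteImage-class].
#' @export
gfpChannel <- function(x) x@gfp

#' @describeIn NeuriteImage-class phospho-NF stand-in channel matrix.
#' @export
phosphoChannel <- function(x) x@phospho

#' @describeIn NeuriteImage-class ground-truth label mask
#'   (0 background, 1 surround, 2 bundle).
#' @export
labelMask <- function(x) x@mask

#' @describeIn NeuriteImage-class day in culture of the frame.
#' @export
imageDay <- function(x) x@day

#' @describeIn NeuriteStack-class list of frames.
#' @param x a [NeuriteStack-class].
#' @export
frames <- function(x) x@frames

#' @describeIn NeuriteStack-class days of the series.
#' @export
stackDays <- function(x) x@days

#' @describeIn BinnedBundleProfile-class the five bin values.
#' @param x a [BinnedBundleProfile-class].
#' @export
binValues <- function(x) x@bins

#' @describeIn DecayFit-class fitted decay coefficient (per day).
#' @param x a [DecayFit-class].
#' @export
decayCoefficient <- function(x) x@lambda

setMethod("show", "NeuritePhantom", function(object) {
  cat("NeuritePhantom: ", object@lengthPx, " x ", object@diameterPx,
      " px neurite, bundle ", object@bundleWidthPx, " px, ",
      nrow(object@varicosities), " varicosit",
      if (nrow(object@varicosities) == 1L) "y" else "ies",
      ", margins ", object@hillockPx, "/", object@growthconePx,
      " px (hillock/growth cone)\n", sep = "")
})

setMethod("show", "CompartmentKinetics", function(object) {
  cat("CompartmentKinetics [", object@compartment, "] N0 = ", object@N0,
      if (object@additive) " (additive over surround)", "\n", sep = "")
  ph <- object@phases
  for (i in seq_len(nrow(ph)))
    cat(sprintf("  days %g-%g: lambda %.4f /day (half-life %s d)\n",
                ph[i, 1L], ph[i, 2L], ph[i, 3L],
                if (ph[i, 3L] > 0) sprintf("%.2f", log(2) / ph[i, 3L]) else "Inf"))
  if (length(object@binLambda))
    cat("  per-bin half-lives (d):",
        paste(sprintf("%.2f", log(2) / object@binLambda), collapse = " "), "\n")
})

setMethod("show", "NeuriteImage", function(object) {
  cat("NeuriteImage day ", object@day, ": ", nrow(object@gfp), " x ",
      ncol(object@gfp), " px, channels gfp/phospho",
      if (object@noisy) " (noisy)" else " (noiseless)", "\n", sep = "")
})

setMethod("show", "NeuriteStack", function(object) {
  cat("NeuriteStack of", length(object@frames), "frame(s), days",
      paste(object@days, collapse = ", "),
      if (!is.null(object@bleach)) "(bleached)", "\n")
})

setMethod("show", "LateralProfile", function(object) {
  cat("LateralProfile at x =", object@locationPx, "px:",
      length(object@positionPx), "positions, channels",
      paste(object@channelNames, collapse = "/"), "\n")
})

setMethod("show", "BundleExtent", function(object) {
  cat(sprintf("BundleExtent [%d, %d) within neurite [%d, %d)\n",
              object@startPx, object@endPx, object@neuriteStartPx,
              object@neuriteEndPx))
})

setMethod("show", "BinnedBundleProfile", function(object) {
  cat("BinnedBundleProfile",
      if (object@normalized) "(edge-normalized)" else "(raw)", "\n")
  print(round(object@bins, 4))
})

setMethod("show", "DecayFit", function(object) {
  cat(sprintf(
    "DecayFit days %g-%g: N0 = %.1f, lambda = %.4f /day, half-life = %s d, r2 = %.4f%s\n",
    object@window[1L], object@window[2L], object@n0, object@lambda,
    if (is.finite(object@halfLifeDays)) sprintf("%.2f", object@halfLifeDays) else "Inf",
    object@rSquared,
    if (object@flag != "ok") paste0(" [", object@flag, "]") else ""))
})

setMethod("show", "BiphasicFit", function(object) {
  cat("BiphasicFit (breakpoint day", object@breakpointDay, ")\n early: ")
  show(object@early)
  cat(" late:  ")
  show(object@late)
})

setMethod("show", "RecoveryResult", function(object) {
  cat(sprintf(
    "RecoveryResult: pre %.1f -> post %.1f -> recovered %.1f (%.1f%% of pre)%s\n",
    object@pre, object@postBleach, object@recovered,
    100 * object@fractionOfPre,
    if (object@flag != "ok") paste0(" [", object@flag, "]") else ""))
})

setMethod("show", "ConditionComparison", function(object) {
  cat(sprintf(
    "%s: %s %.2f (n=%d) vs %s %.2f (n=%d); fold %.2f, t = %.2f, p = %.3g\n",
    object@metric, object@labels[1L], object@means[1L], object@ns[1L],
    object@labels[2L], object@means[2L], object@ns[2L],
    object@foldDifference, object@tStatistic, object@pValue))
})

setMethod("show", "SegmentPartition", function(object) {
  b <- object@bounds
  cat(sprintf("SegmentPartition: proximal [%d,%d) central [%d,%d) distal [%d,%d)\n",
              b[1, 1], b[1, 2], b[2, 1], b[2, 2], b[3, 1], b[3, 2]))
})
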