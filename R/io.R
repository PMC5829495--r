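# TIFF export/import of synthetic stacks with a JSON sidecar carrying the
# generating parameters (the ground truth), and list/JSON serialization of
# the parameter objects.

phantomToList <- function(p) {
  list(lengthPx = p@lengthPx, diameterPx = p@diameterPx,
       bundleWidthPx = p@bundleWidthPx, axisRow = p@axisRow,
       imageHeightPx = p@imageHeightPx,
       varicosities = if (nrow(p@varicosities)) unname(apply(p@varicosities, 1L, as.list, simplify = FALSE)) else list(),
       backgroundLevel = p@backgroundLevel, hillockPx = p@hillockPx,
       growthconePx = p@growthconePx,
       phosphoBundleLevel = p@phosphoBundleLevel,
       phosphoSurroundLevel = p@phosphoSurroundLevel)
}

listToPhantom <- function(x) {
  var <- if (length(x$varicosities))
    do.call(rbind, lapply(x$varicosities, function(v) unlist(v))) else NULL
  NeuritePhantom(lengthPx = x$lengthPx, diameterPx = x$diameterPx,
    bundleWidthPx = x$bundleWidthPx, varicosities = var,
    backgroundLevel = x$backgroundLevel, hillockPx = x$hillockPx,
    growthconePx = x$growthconePx, axisRow = x$axisRow,
    imageHeightPx = x$imageHeightPx,
    phosphoBundleLevel = x$phosphoBundleLevel %||% 1200,
    phosphoSurroundLevel = x$phosphoSurroundLevel %||% 300)
}

kineticsToList <- function(k) {
  list(compartment = k@compartment, N0 = k@N0,
       phases = unname(apply(k@phases, 1L, as.list, simplify = FALSE)),
       spatialProfile = if (length(k@spatialProfile)) k@spatialProfile else NULL,
       binLambda = if (length(k@binLambda)) k@binLambda else NULL,
       additive = k@additive)
}

listToKinetics <- function(x) {
  CompartmentKinetics(x$compartment, x$N0,
    phases = do.call(rbind, lapply(x$phases, unlist)),
    spatialProfile = x$spatialProfile, binLambda = x$binLambda,
    additive = isTRUE(x$additive))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a neurite stack as multi-page 16-bit TIFF plus JSON sidecar
#'
#' Pages are in channel-major order (all GFP frames, then all phospho-NF
#' frames). The sidecar (`<path>.json`) records phantom, kinetics, days and
#' acquisition parameters; on reading, the ground-truth label mask is
#' reconstructed from the phantom geometry.
#'
#' @param stack a [NeuriteStack-class].
#' @param path output TIFF path.
#' @return invisibly, `path`.
#' @export
writeNeuriteStack <- function(stack, path) {
  maxVal <- 2^16 - 1
  pages <- c(lapply(stack@frames, function(f) f@gfp / maxVal),
             lapply(stack@frames, function(f) f@phospho / maxVal))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  sidecar <- list(
    days = stack@days,
    phantom = phantomToList(stack@phantom),
    kinetics = lapply(stack@kinetics, kineticsToList),
    config = list(gaussianReadNoiseSd = stack@config@gaussianReadNoiseSd,
                  poissonNoise = stack@config@poissonNoise,
                  psfSigmaPx = stack@config@psfSigmaPx,
                  seed = stack@config@seed))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a neurite stack written by [writeNeuriteStack()]
#'
#' @param path TIFF path (sidecar `<path>.json` must exist).
#' @return A [NeuriteStack-class].
#' @export
readNeuriteStack <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE,
                              simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  maxVal <- 2^16 - 1
  nFrames <- length(side$days)
  phantom <- listToPhantom(side$phantom)
  kin <- lapply(side$kinetics, listToKinetics)
  cfg <- AcquisitionConfig(gaussianReadNoiseSd = side$config$gaussianReadNoiseSd,
                           poissonNoise = side$config$poissonNoise,
                           psfSigmaPx = side$config$psfSigmaPx,
                           seed = side$config$seed)
  mask <- buildGeometry(phantom)$mask
  frames <- lapply(seq_len(nFrames), function(i) {
    new("NeuriteImage", gfp = round(pages[[i]] * maxVal),
        phospho = round(pages[[nFrames + i]] * maxVal), mask = mask,
        day = side$days[i], phantom = phantom,
        noisy = cfg@poissonNoise || cfg@gaussianReadNoiseSd > 0)
  })
  scale <- matrix(1, 2L, nFrames,
                  dimnames = list(c("bundle", "surround"), NULL))
  new("NeuriteStack", frames = frames, days = as.numeric(side$days),
      phantom = phantom, kinetics = kin, config = cfg, bleach = NULL,
      intensityScale = scale)
}
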