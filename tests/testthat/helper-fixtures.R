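# Shared fixtures: small phantoms and kinetics built in code.

flatPhantom <- function(...) {
  NeuritePhantom(lengthPx = 120L, diameterPx = 15L, bundleWidthPx = 5L,
                 hillockPx = 5L, growthconePx = 5L, backgroundLevel = 0, ...)
}

flatKinetics <- function(bundle = 1000, surround = 400, days = c(0, 4),
                         additive = FALSE) {
  list(CompartmentKinetics("bundle", bundle, c(days[1], days[2], 0),
                           additive = additive),
       CompartmentKinetics("surround", surround, c(days[1], days[2], 0)))
}

noiseless <- function(seed = 1L)
  AcquisitionConfig(gaussianReadNoiseSd = 0, poissonNoise = FALSE,
                    psfSigmaPx = 0, seed = seed)

# profile built directly from a transverse value vector (single channel
# duplicated into gfp/phospho)
profileFromValues <- function(v) {
  new("LateralProfile", positionPx = seq_along(v) - 1L,
      intensity = cbind(gfp = v, phospho = v),
      channelNames = c("gfp", "phospho"), locationPx = 0L)
}

# plateau profile: background tails, surround flanks, central bundle
plateauProfile <- function(bg = 0, surround = 400, bundle = 1000,
                           nBg = 8L, nSur = 5L, nBun = 5L) {
  profileFromValues(c(rep(bg, nBg), rep(surround, nSur), rep(bundle, nBun),
                      rep(surround, nSur), rep(bg, nBg)))
}
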