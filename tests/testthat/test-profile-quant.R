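# Lateral profiles, bundle/surround separation, binning and segmentation.

test_that("profile extraction averages the longitudinal window", {
  ph <- flatPhantom()
  img <- renderNeuriteImage(ph, flatKinetics(), 1, config = noiseless())
  prof <- extractLateralProfile(img, 60L)
  ## flat image columns -> profile equals any single column
  expect_equal(prof@intensity[, "gfp"], gfpChannel(img)[, 61])
  ## halfwidth 0 equals the single pixel column
  prof0 <- extractLateralProfile(img, 60L, halfwidthPx = 0L)
  expect_equal(prof0@intensity[, "gfp"], gfpChannel(img)[, 61])
  expect_error(extractLateralProfile(img, 500L), "outside image")
  expect_warning(extractLateralProfile(img, 1L), "trimmed")
  ## uniform image -> flat profile
  kinU <- flatKinetics(bundle = 700, surround = 700)
  imgU <- renderNeuriteImage(ph, kinU, 1, config = noiseless())
  profU <- extractLateralProfile(imgU, 60L)
  inside <- profU@intensity[, "gfp"] > 0
  expect_true(all(profU@intensity[inside, "gfp"] == 700))
})

test_that("bundle extent detection matches the ground-truth mask", {
  ph <- flatPhantom()
  img <- renderNeuriteImage(ph, flatKinetics(), 1, config = noiseless())
  prof <- extractLateralProfile(img, 60L)
  ext <- detectBundleExtent(prof)
  truth <- range(which(labelMask(img)[, 61] == 2L)) - 1L
  expect_lte(abs(ext@startPx - truth[1L]), 1L)
  expect_lte(abs(ext@endPx - (truth[2L] + 1L)), 1L)
  ## noisy detection stays within 1 px per side
  imgN <- renderNeuriteImage(ph, flatKinetics(), 1,
                             config = AcquisitionConfig(seed = 2L))
  extN <- detectBundleExtent(extractLateralProfile(imgN, 60L))
  expect_lte(abs(extN@startPx - truth[1L]), 1L)
  expect_lte(abs(extN@endPx - (truth[2L] + 1L)), 1L)
})

test_that("flat and bundle-less profiles raise 'no bundle detected'", {
  expect_error(detectBundleExtent(profileFromValues(rep(5, 30))),
               "no bundle detected")
  ## neurite present but no central enrichment
  expect_error(detectBundleExtent(plateauProfile(bundle = 400)),
               "no bundle detected")
})

test_that("the supra-threshold run containing the midline wins", {
  ## two disjoint bright runs; only one straddles the neurite midline
  v <- c(rep(0, 8), rep(400, 4), 900, 400, 400, 900, 900, 900,
         rep(400, 6), rep(0, 8))
  ext <- detectBundleExtent(profileFromValues(v))
  ## the central run (0-based pixels 15..17), not the spurious one at 12
  expect_equal(ext@startPx, 15L)
  expect_equal(ext@endPx, 18L)
  expect_gt(ext@startPx, ext@neuriteStartPx)
  expect_lt(ext@endPx, ext@neuriteEndPx)
})

test_that("surround correction averages both flanks and keeps negatives", {
  prof <- plateauProfile()
  ext <- detectBundleExtent(prof)
  sc <- surroundCorrectedBundle(prof, ext)
  expect_equal(sc$bundle[sc$channel == "gfp"], 600)
  expect_equal(sc$surround[sc$channel == "gfp"], 400)
  ## asymmetric flanks 300/500 average to 400
  v <- c(rep(0, 8), rep(300, 5), rep(1000, 5), rep(500, 5), rep(0, 8))
  scA <- surroundCorrectedBundle(profileFromValues(v),
                                 detectBundleExtent(profileFromValues(v)))
  expect_equal(scA$surround[scA$channel == "gfp"], 400)
  expect_equal(scA$bundle[scA$channel == "gfp"], 600)
  ## a bundle dimmer than its flanks is negative and flagged
  ext2 <- new("BundleExtent", startPx = 13L, endPx = 18L,
              neuriteStartPx = 8L, neuriteEndPx = 23L)
  vNeg <- c(rep(0, 8), rep(500, 5), rep(450, 5), rep(500, 5), rep(0, 8))
  scN <- surroundCorrectedBundle(profileFromValues(vNeg), ext2)
  expect_lt(scN$bundle[1L], 0)
  expect_true(all(scN$negative))
})

test_that("five-bin binning is exact, conservative and normalizable", {
  prof <- plateauProfile()
  ext <- detectBundleExtent(prof)
  ## flat bundle: normalized bins are all 1
  expect_equal(unname(binValues(binBundle(prof, ext, normalize = TRUE))),
               rep(1, 5))
  ## width exactly 5 px: each bin is one pixel value
  vals <- c(rep(0, 8), rep(400, 5), 910, 920, 930, 940, 950, rep(400, 5),
            rep(0, 8))
  prof5 <- profileFromValues(vals)
  ext5 <- new("BundleExtent", startPx = 13L, endPx = 18L,
              neuriteStartPx = 8L, neuriteEndPx = 23L)
  expect_equal(unname(binValues(binBundle(prof5, ext5))),
               c(910, 920, 930, 940, 950))
  ## triangular bundle: center > interior > edge, edges normalize to 1
  tri <- c(rep(0, 8), rep(200, 4), 300, 500, 700, 900, 1000, 900, 700, 500,
           300, rep(200, 4), rep(0, 8))
  profT <- profileFromValues(tri)
  extT <- new("BundleExtent", startPx = 12L, endPx = 21L,
              neuriteStartPx = 8L, neuriteEndPx = 25L)
  bT <- binValues(binBundle(profT, extT))
  expect_gt(bT[["bin_center"]], bT[["bin_int_l"]])
  expect_gt(bT[["bin_int_l"]], bT[["bin_edge_l"]])
  bTn <- binValues(binBundle(profT, extT, normalize = TRUE))
  expect_equal(mean(bTn[c(1L, 5L)]), 1, tolerance = 1e-12)
  expect_error(binBundle(prof5, new("BundleExtent", startPx = 13L,
                                    endPx = 17L, neuriteStartPx = 8L,
                                    neuriteEndPx = 23L)), "too narrow")
})

test_that("bin values agree with an independent sub-pixel integration oracle", {
  set.seed(202)
  for (i in 1:100) {
    w <- sample(5:23, 1L)
    v <- stats::runif(w, 0, 1000)
    prof <- profileFromValues(c(rep(0, 6), rep(50, 3), v, rep(50, 3),
                                rep(0, 6)))
    ext <- new("BundleExtent", startPx = 9L, endPx = 9L + w,
               neuriteStartPx = 6L, neuriteEndPx = as.integer(12L + w))
    bins <- binValues(binBundle(prof, ext))
    ## oracle: linear interpolation of the cumulative pixel integral
    Fcum <- stats::approxfun(0:w, c(0, cumsum(v)))
    bounds <- seq(0, w, length.out = 6L)
    oracle <- diff(Fcum(bounds)) / (w / 5)
    expect_equal(unname(bins), oracle, tolerance = 1e-9)
    ## conservation: mean of raw bins equals the mean over the extent
    expect_equal(mean(bins), mean(v), tolerance = 1e-9)
  }
})

test_that("segment partition follows the remainder rule", {
  p1 <- partitionSegments(300, 0, 0)
  expect_equal(unname(p1@bounds),
               matrix(c(0, 100, 100, 200, 200, 300), 3, byrow = TRUE))
  p2 <- partitionSegments(310, 5, 5)
  expect_equal(unname(p2@bounds[, 2] - p2@bounds[, 1]), c(100, 100, 100))
  expect_equal(unname(p2@bounds[1, 1]), 5)
  expect_equal(unname(p2@bounds[3, 2]), 305)
  p3 <- partitionSegments(301, 0, 0)
  expect_equal(unname(p3@bounds[, 2] - p3@bounds[, 1]), c(100, 100, 101))
  expect_error(partitionSegments(5, 2, 2), "analyzable length")
})

test_that("measureCell recovers generator trajectories on noiseless input", {
  ph <- flatPhantom()
  lam <- log(2) / 5
  kin <- list(CompartmentKinetics("bundle", 600, c(2, 10, lam), additive = TRUE),
              CompartmentKinetics("surround", 1500, c(2, 10, 2 * lam)))
  st <- renderTimeSeries(ph, kin, c(2, 6, 10), config = noiseless())
  meas <- measureCell(st)
  for (d in c(2, 6, 10)) {
    b <- meas$intensity[meas$day == d & meas$compartment == "bundle" &
                          meas$channel == "gfp"]
    s <- meas$intensity[meas$day == d & meas$compartment == "surround" &
                          meas$channel == "gfp"]
    expect_equal(mean(b), 600 * exp(-lam * (d - 2)), tolerance = 0.01)
    expect_equal(mean(s), 1500 * exp(-2 * lam * (d - 2)), tolerance = 0.01)
  }
  ## single-frame input gives single-day records
  m1 <- measureCell(renderTimeSeries(ph, kin, 6, config = noiseless()))
  expect_equal(unique(m1$day), 6)
})

test_that("centrally-suppressed bundle GFP scores below the phospho channel", {
  ph <- flatPhantom()
  kin <- list(CompartmentKinetics("bundle", 400, c(0, 4, 0),
                                  spatialProfile = c(1.3, 1.1, 0.2, 1.1, 1.3),
                                  additive = TRUE),
              CompartmentKinetics("surround", 1000, c(0, 4, 0)))
  img <- renderNeuriteImage(ph, kin, 1, config = noiseless())
  prof <- extractLateralProfile(img, 60L)
  ext <- detectBundleExtent(prof)
  gNorm <- binValues(binBundle(prof, ext, normalize = TRUE, channel = "gfp"))
  pNorm <- binValues(binBundle(prof, ext, normalize = TRUE, channel = "phospho"))
  expect_lt(gNorm[["bin_center"]], pNorm[["bin_center"]])
})
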