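# Synthetic-neurite generator: compartment-mean fidelity, noise model,
# seed determinism, trajectory continuity and the bleach model.

test_that("noiseless compartment means equal the analytic trajectories", {
  ph <- flatPhantom()
  img <- renderNeuriteImage(ph, flatKinetics(), day = 2, config = noiseless())
  expect_equal(mean(gfpChannel(img)[labelMask(img) == 2L]), 1000)
  expect_equal(mean(gfpChannel(img)[labelMask(img) == 1L]), 400)

  ## one half-life halves the intensity
  kin <- list(CompartmentKinetics("bundle", 1000, c(0, 4, log(2))),
              CompartmentKinetics("surround", 400, c(0, 4, 0)))
  img1 <- renderNeuriteImage(ph, kin, day = 1, config = noiseless())
  expect_equal(mean(gfpChannel(img1)[labelMask(img1) == 2L]), 500)

  ## relative error below 1e-6 for a generic decayed value
  img2 <- renderNeuriteImage(ph, kin, day = 2.37, config = noiseless())
  expect_equal(mean(gfpChannel(img2)[labelMask(img2) == 2L]),
               1000 * exp(-log(2) * 2.37), tolerance = 1e-6)
})

test_that("day outside the kinetics support is rejected", {
  ph <- flatPhantom()
  expect_error(renderNeuriteImage(ph, flatKinetics(days = c(2, 4)), day = 7,
                                  config = noiseless()),
               "day outside kinetics support")
  expect_error(NeuritePhantom(diameterPx = 9L, bundleWidthPx = 9L),
               "bundleWidthPx")
})

test_that("noisy compartment means stay within 3 SE of the noiseless means", {
  ph <- flatPhantom()
  kin <- flatKinetics()
  cfg <- AcquisitionConfig(gaussianReadNoiseSd = 10, poissonNoise = TRUE,
                           seed = 7L)
  img <- renderNeuriteImage(ph, kin, day = 1, config = cfg)
  for (lab in c(1L, 2L)) {
    mu <- c(400, 1000)[lab]
    px <- gfpChannel(img)[labelMask(img) == lab]
    se <- sqrt((mu + 100) / length(px))
    expect_lt(abs(mean(px) - mu), 3 * se)
  }
  ## bit-exact reproducibility under the same seed
  img2 <- renderNeuriteImage(ph, kin, day = 1, config = cfg)
  expect_identical(gfpChannel(img), gfpChannel(img2))
  expect_identical(phosphoChannel(img), phosphoChannel(img2))
  ## a different seed gives different pixels
  cfg2 <- cfg; cfg2@seed <- 8L
  expect_false(identical(gfpChannel(img),
                         gfpChannel(renderNeuriteImage(ph, kin, 1, cfg2))))
})

test_that("time series follow the closed form and are continuous at breakpoints", {
  ph <- flatPhantom()
  lam <- log(2) / 5.5
  kin <- list(CompartmentKinetics("bundle", 1000, c(2, 14, lam)),
              CompartmentKinetics("surround", 5000, rbind(
                c(2, 4, log(2) / 0.9), c(4, 14, log(2) / 5.7))))
  st <- renderTimeSeries(ph, kin, c(2, 4, 7, 14), config = noiseless())
  for (i in seq_along(stackDays(st))) {
    f <- frames(st)[[i]]
    expect_equal(mean(gfpChannel(f)[labelMask(f) == 2L]),
                 1000 * exp(-lam * (stackDays(st)[i] - 2)), tolerance = 1e-9)
  }
  ## continuity: value at the day-4 breakpoint equals the early-phase limit
  expect_equal(compartmentIntensity(kin[[2]], 4),
               5000 * exp(-log(2) / 0.9 * 2), tolerance = 1e-12)
  expect_equal(compartmentIntensity(kin[[2]], 4 + 1e-9),
               compartmentIntensity(kin[[2]], 4 - 1e-9), tolerance = 1e-6)
  ## single-day series matches the single-frame renderer
  st1 <- renderTimeSeries(ph, kin, 7, config = AcquisitionConfig(seed = 3))
  img <- renderNeuriteImage(ph, kin, 7, config = AcquisitionConfig(seed = 3))
  expect_identical(gfpChannel(frames(st1)[[1L]]), gfpChannel(img))
  expect_error(renderTimeSeries(ph, kin, numeric(0)), "non-empty")
  expect_error(renderTimeSeries(ph, kin, c(4, 2)), "strictly increasing")
})

test_that("the bleach model destroys, pins and recovers as specified", {
  k <- function(comp, n0) CompartmentKinetics(comp, n0, c(0, 10, 0))
  mk <- function(eff, sr, br) BleachSpec(10L, 40L, bleachDay = 5,
    efficiency = eff, surroundRecoveryFraction = sr,
    bundleRecoveryFraction = br, recoveryDelayDays = 0.5)
  ## efficiency 1, surround recovery 0.9
  b <- mk(1, 0.9, 0)
  expect_equal(bleachedTrajectory(k("surround", 200), c(5, 5.2), b), c(0, 0))
  expect_equal(bleachedTrajectory(k("surround", 200), 6, b), 180)
  ## efficiency 0 leaves everything unchanged
  b0 <- mk(0, 0.9, 0)
  expect_equal(bleachedTrajectory(k("surround", 200), c(4, 5, 6), b0),
               rep(200, 3))
  expect_equal(bleachedTrajectory(k("bundle", 300), c(4, 5, 6), b0),
               rep(300, 3))
  ## efficiency 0.8, bundle recovery 0 -> post-recovery 0.2 x pre
  b8 <- mk(0.8, 0.9, 0)
  expect_equal(bleachedTrajectory(k("bundle", 500), 6, b8), 100)
})

test_that("pixels outside the bleached region are untouched at every day", {
  ph <- flatPhantom()
  kin <- flatKinetics(days = c(0, 10))
  cfg <- AcquisitionConfig(seed = 11L)
  st <- renderTimeSeries(ph, kin, c(4, 5, 6), config = cfg)
  bl <- BleachSpec(40L, 80L, bleachDay = 5, efficiency = 0.9)
  stB <- applyBleach(st, bl)
  outside <- c(1:40, 81:120)
  for (i in 1:3) {
    expect_identical(gfpChannel(frames(st)[[i]])[, outside],
                     gfpChannel(frames(stB)[[i]])[, outside])
    expect_identical(phosphoChannel(frames(st)[[i]])[, outside],
                     phosphoChannel(frames(stB)[[i]])[, outside])
  }
  ## inside the region the bleached frames differ after the bleach day
  expect_false(identical(gfpChannel(frames(st)[[2L]])[, 41:80],
                         gfpChannel(frames(stB)[[2L]])[, 41:80]))
  expect_error(applyBleach(st, BleachSpec(40L, 500L, 5)), "region outside")
  expect_error(applyBleach(st, BleachSpec(40L, 80L, 20)), "time support")
})

test_that("emitProfileTable matches the closed form and its noise is unbiased", {
  lam <- log(2) / 3
  kin <- list(CompartmentKinetics("bundle", 800, c(1, 9, lam)),
              CompartmentKinetics("surround", 2000, c(1, 9, 2 * lam)))
  tab <- emitProfileTable(kin, days = c(1, 3, 9), perCellNoiseCv = 0,
                          nCells = 1)
  expect_equal(tab$intensity[tab$compartment == "bundle"],
               800 * exp(-lam * (c(1, 3, 9) - 1)))
  ## Monte-Carlo: per-day sample mean within 3 SE of the closed form
  tabN <- emitProfileTable(kin, days = c(1, 3, 9), perCellNoiseCv = 0.1,
                           nCells = 200, seed = 5)
  for (d in c(1, 3, 9)) {
    mu <- 2000 * exp(-2 * lam * (d - 1))
    x <- tabN$intensity[tabN$compartment == "surround" & tabN$day == d]
    expect_lt(abs(mean(x) - mu), 3 * mu * 0.1 / sqrt(200))
  }
  expect_error(emitProfileTable(kin, 1, nCells = 0), "nCells")
  expect_error(emitProfileTable(kin, 1, perCellNoiseCv = -0.1), "Cv")
  ## determinism
  expect_identical(emitProfileTable(kin, c(1, 3), 0.1, 10, seed = 9),
                   emitProfileTable(kin, c(1, 3), 0.1, 10, seed = 9))
})

test_that("varicosity positions are validated and widen only the surround", {
  expect_error(NeuritePhantom(varicosities = cbind(2, 6), hillockPx = 5L),
               "varicosity positions")
  ph <- NeuritePhantom(lengthPx = 120L, varicosities = cbind(60, 8),
                       hillockPx = 5L, growthconePx = 5L, backgroundLevel = 0)
  img <- renderNeuriteImage(ph, flatKinetics(), 1, config = noiseless())
  m <- labelMask(img)
  ## more surround rows at the varicosity than at the far end
  expect_gt(sum(m[, 61] == 1L), sum(m[, 10] == 1L))
  ## bundle width unchanged
  expect_equal(sum(m[, 61] == 2L), sum(m[, 10] == 2L))
})

test_that("TIFF round trip preserves pixels and sidecar parameters", {
  ph <- flatPhantom()
  st <- renderTimeSeries(ph, flatKinetics(), c(1, 2),
                         config = AcquisitionConfig(seed = 4L))
  path <- file.path(tempdir(), "stack.tif")
  writeNeuriteStack(st, path)
  rt <- readNeuriteStack(path)
  expect_equal(stackDays(rt), c(1, 2))
  expect_equal(gfpChannel(frames(rt)[[1L]]), gfpChannel(frames(st)[[1L]]))
  expect_equal(phosphoChannel(frames(rt)[[2L]]), phosphoChannel(frames(st)[[2L]]))
  expect_identical(labelMask(frames(rt)[[1L]]), labelMask(frames(st)[[1L]]))
})
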