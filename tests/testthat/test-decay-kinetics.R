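# Decay fitting, half-lives, decline rates and recovery metrics.

test_that("two-point fits reduce to the closed form", {
  fit <- fitExponential(data.frame(day = c(2, 4), mean = c(1000, 250)))
  expect_equal(fit@lambda, log(4) / 2, tolerance = 1e-12)
  expect_equal(halfLife(fit), 1, tolerance = 1e-12)
  expect_equal(fit@n0, 1000, tolerance = 1e-9)
  expect_equal(fit@t0, 2)
  ## fitted curve at t0 equals N0 by construction
  expect_equal(fit@n0 * exp(-fit@lambda * 0), fit@n0)
})

test_that("constant and non-positive series are handled", {
  fit <- fitExponential(data.frame(day = 1:4, mean = rep(500, 4)))
  expect_equal(fit@lambda, 0, tolerance = 1e-12)
  expect_identical(fit@flag, "no decay")
  expect_true(is.infinite(halfLife(fit)))
  expect_error(fitExponential(data.frame(day = 1:3, mean = c(5, -1, 2))),
               "log-linear fit undefined")
  expect_error(fitExponential(data.frame(day = 1, mean = 5)), "at least 2")
})

test_that("noiseless generator series are recovered to machine precision", {
  lam <- log(2) / 5.5
  days <- c(2, 4, 7, 14)
  s <- data.frame(day = days, mean = 1234 * exp(-lam * (days - 2)))
  fit <- fitExponential(s)
  expect_equal(fit@lambda, lam, tolerance = 1e-12)
  expect_equal(halfLife(fit), 5.5, tolerance = 1e-9)
  expect_equal(fit@rSquared, 1, tolerance = 1e-9)
})

test_that("half-life is ln(2)/lambda, monotone, and flags lambda <= 0", {
  expect_equal(halfLife(log(2)), 1)
  expect_equal(halfLife(log(2) / 5.5), 5.5)
  lams <- sort(stats::runif(20, 0.01, 2))
  expect_true(all(diff(halfLife(lams)) < 0))
  expect_warning(hl0 <- halfLife(0), "non-positive")
  expect_true(is.infinite(hl0))
})

test_that("biphasic fits recover both phases and share the breakpoint", {
  lamE <- log(2) / 0.9
  lamL <- log(2) / 5.7
  days <- c(2, 3, 4, 7, 14)
  n4 <- 5000 * exp(-lamE * 2)
  mean <- ifelse(days <= 4, 5000 * exp(-lamE * (days - 2)),
                 n4 * exp(-lamL * (days - 4)))
  bi <- fitBiphasic(data.frame(day = days, mean = mean), breakpointDay = 4)
  expect_equal(halfLife(bi@early), 0.9, tolerance = 1e-9)
  expect_equal(halfLife(bi@late), 5.7, tolerance = 1e-9)
  expect_equal(bi@early@window[2L], 4)
  expect_equal(bi@late@window[1L], 4)
  ## single-phase data: both phases agree with the mono-exponential fit
  one <- data.frame(day = days, mean = 2000 * exp(-0.2 * (days - 2)))
  biOne <- fitBiphasic(one, 4)
  expect_equal(halfLife(biOne@early), halfLife(biOne@late), tolerance = 1e-9)
  expect_equal(halfLife(biOne@early), halfLife(fitExponential(one)),
               tolerance = 1e-9)
  expect_error(fitBiphasic(one, 20), "breakpoint outside")
})

test_that("decline rates match closed forms and a finite-difference oracle", {
  fit <- fitExponential(data.frame(day = 0:1, mean = c(1000, 500)))
  expect_equal(declineRate(fit, 0), log(2) * 1000, tolerance = 1e-9)
  expect_equal(round(declineRate(fit, 0), 1), 693.1)
  expect_equal(declineRate(fit, 0, "daily"), 500, tolerance = 1e-9)
  ## lambda 0 -> rate 0
  f0 <- fitExponential(data.frame(day = 0:1, mean = c(7, 7)))
  expect_equal(declineRate(f0, 0), 0)
  ## centered finite difference of the fitted curve
  nAt <- function(d) fit@n0 * exp(-fit@lambda * d)
  h <- 1e-6
  expect_equal(declineRate(fit, 0.7),
               -(nAt(0.7 + h) - nAt(0.7 - h)) / (2 * h), tolerance = 1e-6)
  ## ratios: identical fits give 1; zero denominator errors
  expect_equal(declineRateRatio(fit, fit, 0.3), 1)
  expect_error(declineRateRatio(fit, f0, 0), "zero denominator")
})

test_that("scaling a series rescales N0 but not lambda or rate ratios", {
  days <- c(2, 4, 7, 14)
  s <- data.frame(day = days, mean = 900 * exp(-0.31 * (days - 2)))
  s2 <- transform(s, mean = mean * 37.5)
  f1 <- fitExponential(s)
  f2 <- fitExponential(s2)
  expect_equal(f2@lambda, f1@lambda, tolerance = 1e-12)
  expect_equal(halfLife(f2), halfLife(f1), tolerance = 1e-12)
  expect_equal(f2@n0, 37.5 * f1@n0, tolerance = 1e-9)
  expect_equal(declineRateRatio(f1, f1, 3), declineRateRatio(f2, f2, 3))
})

test_that("per-bin half-lives fit the three regions and reject normalized bins", {
  lam <- c(edge = log(2) / 6.7, interior = log(2) / 6.2, center = log(2) / 6.5)
  kin <- list(CompartmentKinetics("bundle", 1000, c(4, 14, lam["center"]),
                spatialProfile = c(0.7, 0.85, 1, 0.85, 0.7),
                binLambda = unname(lam[c("edge", "interior", "center",
                                          "interior", "edge")])),
              CompartmentKinetics("surround", 500, c(4, 14, 0.1)))
  tab <- emitProfileTable(kin, c(4, 7, 14), perCellNoiseCv = 0, nCells = 2)
  fits <- perBinHalfLives(tab, window = c(4, 14))
  expect_equal(halfLife(fits$center), 6.5, tolerance = 1e-6)
  expect_equal(halfLife(fits$interior), 6.2, tolerance = 1e-6)
  expect_equal(halfLife(fits$edge), 6.7, tolerance = 1e-6)
  ## equal per-bin coefficients give three equal half-lives
  kinEq <- list(CompartmentKinetics("bundle", 1000, c(4, 14, 0.2),
                  binLambda = rep(0.2, 5)),
                kin[[2L]])
  tabEq <- emitProfileTable(kinEq, c(4, 7, 14), 0, 2)
  hl <- vapply(perBinHalfLives(tabEq, window = c(4, 14)), halfLife, numeric(1))
  expect_equal(unname(hl), rep(log(2) / 0.2, 3), tolerance = 1e-9)
  ## normalized bins are rejected, both by flag and by detection
  expect_error(perBinHalfLives(tab, normalized = TRUE), "normalized bins")
  tabN <- tab
  for (d in unique(tabN$day)) {
    sel <- tabN$day == d & grepl("^bin_", tabN$compartment)
    em <- mean(tabN$intensity[sel & tabN$compartment %in%
                                c("bin_edge_l", "bin_edge_r")])
    tabN$intensity[sel] <- tabN$intensity[sel] / em
  }
  expect_error(perBinHalfLives(tabN), "normalized bins")
})

test_that("recovery metrics implement both fractions and flag odd inputs", {
  r <- recoveryMetrics(100, 10, 92)
  expect_equal(r@fractionOfPre, 0.92)
  expect_equal(r@fractionOfLost, (92 - 10) / 90)
  expect_equal(recoveryMetrics(100, 10, 10)@fractionOfLost, 0)
  rFull <- recoveryMetrics(100, 0, 100)
  expect_equal(rFull@fractionOfPre, 1)
  expect_equal(rFull@fractionOfLost, 1)
  expect_error(recoveryMetrics(0, 1, 2), "must be > 0")
  expect_identical(recoveryMetrics(100, 120, 110)@flag, "no bleach detected")
})

test_that("fitted half-lives stay within 10% of truth across seeds (cv 0.15)", {
  lamB <- log(2) / 5.5
  kin <- list(CompartmentKinetics("bundle", 1000, c(2, 14, lamB)),
              CompartmentKinetics("surround", 5000, rbind(
                c(2, 4, log(2) / 0.9), c(4, 14, log(2) / 5.7))))
  for (sd in 1:20) {
    tab <- emitProfileTable(kin, c(2, 4, 7, 14), perCellNoiseCv = 0.15,
                            nCells = 30, seed = sd)
    hb <- halfLife(fitExponential(aggregateSeries(tab, "bundle")))
    hsE <- halfLife(fitExponential(aggregateSeries(tab, "surround"),
                                   window = c(2, 4)))
    hsL <- halfLife(fitExponential(aggregateSeries(tab, "surround"),
                                   window = c(4, 14)))
    expect_lt(abs(hb - 5.5) / 5.5, 0.10)
    expect_lt(abs(hsE - 0.9) / 0.9, 0.10)
    expect_lt(abs(hsL - 5.7) / 5.7, 0.10)
  }
})

test_that("cell-level bootstrap brackets the point estimate", {
  kin <- list(CompartmentKinetics("bundle", 1000, c(2, 14, log(2) / 5.5)),
              CompartmentKinetics("surround", 4000, c(2, 14, log(2) / 2)))
  tab <- emitProfileTable(kin, c(2, 4, 7, 14), perCellNoiseCv = 0.1,
                          nCells = 25, seed = 6)
  bs <- bootstrapHalfLife(tab, "bundle", reps = 200L, seed = 9L)
  expect_true(bs$ci[1L] < bs$halfLife && bs$halfLife < bs$ci[2L])
  expect_lt(bs$se / bs$halfLife, 0.2)
})
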