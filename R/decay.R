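# Mono- and bi-phasic exponential decay fitting, half-lives, decline rates
# and photobleach-recovery metrics.

asSeries <- function(series) {
  if (is.data.frame(series)) {
    val <- if ("mean" %in% names(series)) series$mean else series$intensity
    if (is.null(val)) stop("series must have a 'mean' or 'intensity' column")
    data.frame(day = series$day, mean = val)
  } else stop("series must be a data.frame")
}

#' Fit a mono-exponential decay by log-linear least squares
#'
#' Ordinary least squares of `log(mean intensity)` on `day - t0` over the
#' requested window, with `t0` the first day of the window:
#' `lambda = -slope`, `N0 = exp(intercept)`, half-life `ln(2)/lambda`.
#' On noiseless exponential input the generating coefficient is recovered
#' exactly. A window of two days reduces to the two-point closed form.
#'
#' @param series data.frame with columns `day` and `mean` (or `intensity`),
#'   e.g. from [aggregateSeries()].
#' @param window optional `c(firstDay, lastDay)` inclusive; default all days.
#' @param weights optional per-day weights (e.g. cell counts `n`); default
#'   unweighted.
#' @return A [DecayFit-class]. A non-positive fitted `lambda` gives an
#'   infinite half-life and flag `"no decay"`.
#' @examples
#' fit <- fitExponential(data.frame(day = c(2, 4), mean = c(1000, 250)))
#' halfLife(fit)  # 1 day
#' @export
fitExponential <- function(series, window = NULL, weights = NULL) {
  s <- asSeries(series)
  if (!is.null(weights)) s$w <- weights
  if (!is.null(window))
    s <- s[s$day >= window[1L] - 1e-9 & s$day <= window[2L] + 1e-9, , drop = FALSE]
  if (nrow(s) < 2L) stop("need at least 2 days in the fit window")
  if (any(s$mean <= 0))
    stop("log-linear fit undefined; check background subtraction")
  s <- s[order(s$day), , drop = FALSE]
  t0 <- s$day[1L]
  x <- s$day - t0
  y <- log(s$mean)
  fit <- if (is.null(weights)) stats::lm(y ~ x) else stats::lm(y ~ x, weights = s$w)
  co <- stats::coef(fit)
  lambda <- -co[[2L]]
  tss <- sum((y - mean(y))^2)
  rsq <- if (nrow(s) == 2L || tss < 1e-24) 1
         else 1 - sum(stats::residuals(fit)^2) / tss
  new("DecayFit", n0 = exp(co[[1L]]), lambda = lambda,
      halfLifeDays = if (lambda > 0) log(2) / lambda else Inf,
      t0 = t0, rSquared = rsq, window = range(s$day),
      flag = if (lambda > 1e-12) "ok" else "no decay")
}

#' Half-life from a decay coefficient or fit
#'
#' `ln(2) / lambda` in days. A non-positive coefficient has no finite
#' half-life and returns `Inf` with a warning.
#'
#' @param x a decay coefficient (per day) or a [DecayFit-class].
#' @param ... unused.
#' @return half-life in days.
#' @examples
#' halfLife(log(2))        # 1
#' halfLife(log(2) / 5.5)  # 5.5
#' @export
setGeneric("halfLife", function(x, ...) standardGeneric("halfLife"))

#' @rdname halfLife
#' @export
setMethod("halfLife", "numeric", function(x, ...) {
  out <- ifelse(x > 0, log(2) / x, Inf)
  if (any(x <= 0)) warning("non-positive decay coefficient: half-life undefined (Inf)")
  out
})

#' @rdname halfLife
#' @export
setMethod("halfLife", "DecayFit", function(x, ...) x@halfLifeDays)

#' Fit a bi-phasic decay with a fixed breakpoint
#'
#' Two independent [fitExponential()] calls on the windows
#' `[first day, breakpoint]` and `[breakpoint, last day]`; the breakpoint
#' observation contributes to both fits.
#'
#' @inheritParams fitExponential
#' @param breakpointDay the fixed phase boundary (default day 4).
#' @return A [BiphasicFit-class].
#' @export
fitBiphasic <- function(series, breakpointDay = 4) {
  s <- asSeries(series)
  if (breakpointDay <= min(s$day) || breakpointDay >= max(s$day))
    stop("breakpoint outside data range")
  early <- fitExponential(s, window = c(min(s$day), breakpointDay))
  late <- fitExponential(s, window = c(breakpointDay, max(s$day)))
  new("BiphasicFit", early = early, late = late,
      breakpointDay = as.numeric(breakpointDay))
}

#' Decline rate of a fitted decay at a given day
#'
#' `"instantaneous"` (default) is the magnitude of the derivative of the
#' fitted curve, `lambda * N0 * exp(-lambda (day - t0))` — a positive loss
#' per day. `"daily"` is the fitted per-day decrement
#' `N(day) - N(day + 1)`, the decline-per-day read off consecutive daily
#' observations; compartment rate ratios quoted from daily sampling
#' correspond to this definition.
#'
#' @param fit a [DecayFit-class].
#' @param day day at which to evaluate (within or adjacent to the fit
#'   window).
#' @param method `"instantaneous"` or `"daily"`.
#' @return intensity loss per day (a.u./day).
#' @examples
#' f <- fitExponential(data.frame(day = 0:1, mean = c(1000, 500)))
#' declineRate(f, 0)            # ln(2) * 1000 = 693.1
#' declineRate(f, 0, "daily")   # 1000 - 500 = 500
#' @export
declineRate <- function(fit, day, method = c("instantaneous", "daily")) {
  method <- match.arg(method)
  nAt <- function(d) fit@n0 * exp(-fit@lambda * (d - fit@t0))
  switch(method,
    instantaneous = fit@lambda * nAt(day),
    daily = nAt(day) - nAt(day + 1))
}

#' Ratio of two compartments' decline rates
#'
#' @param fitA,fitB [DecayFit-class] objects (numerator, denominator).
#' @inheritParams declineRate
#' @return dimensionless ratio.
#' @export
declineRateRatio <- function(fitA, fitB, day,
                             method = c("instantaneous", "daily")) {
  den <- declineRate(fitB, day, method)
  if (abs(den) < 1e-12 * max(1, fitB@n0)) stop("zero denominator decline rate")
  declineRate(fitA, day, method) / den
}

#' Half-lives of the bundle's transverse regions
#'
#' Fits the center bin, the pairwise-averaged interior bins and the
#' pairwise-averaged edge bins of the raw (unnormalized) five-bin series.
#' Normalized bins carry no decay information (the edges are pinned to 1)
#' and are rejected.
#'
#' @param measurements measurement table containing raw bin records
#'   ([measureCell()] / [simulateCohort()] / [emitProfileTable()]).
#' @param window optional fit window `c(firstDay, lastDay)`.
#' @param normalized set to `TRUE` only to assert what you are passing —
#'   normalized bins are rejected with an error. Edge-normalized input is
#'   also detected and rejected.
#' @param channel channel to use.
#' @return named list of [DecayFit-class]: `center`, `interior`, `edge`.
#' @export
perBinHalfLives <- function(measurements, window = NULL, normalized = FALSE,
                            channel = "gfp") {
  if (isTRUE(normalized))
    stop("normalized bins cannot be used for decay fitting; supply raw bin intensities")
  edges <- binRegionSeries(measurements, "edge", channel = channel)
  if (all(abs(edges$mean - 1) < 1e-6))
    stop("normalized bins cannot be used for decay fitting; supply raw bin intensities")
  lapply(stats::setNames(c("center", "interior", "edge"),
                         c("center", "interior", "edge")),
         function(r) fitExponential(
           binRegionSeries(measurements, r, channel = channel), window = window))
}

#' Photobleach-recovery metrics
#'
#' @param pre intensity prior to photobleaching (> 0).
#' @param postBleach intensity immediately after photobleaching.
#' @param recovered intensity 10-12 h after photobleaching.
#' @return A [RecoveryResult-class] with `recovered/pre` and
#'   `(recovered - postBleach)/(pre - postBleach)`; flagged
#'   `"no bleach detected"` when `postBleach > pre`.
#' @examples
#' recoveryMetrics(100, 10, 92)  # fractionOfPre 0.92
#' @export
recoveryMetrics <- function(pre, postBleach, recovered) {
  if (pre <= 0) stop("pre-bleach intensity must be > 0")
  lost <- pre - postBleach
  new("RecoveryResult", pre = pre, postBleach = postBleach,
      recovered = recovered, fractionOfPre = recovered / pre,
      fractionOfLost = if (lost > 0) (recovered - postBleach) / lost else NA_real_,
      flag = if (postBleach > pre) "no bleach detected" else "ok")
}

#' Bootstrap confidence interval for a fitted half-life
#'
#' Cell-level bootstrap: cells are resampled with replacement, per-day
#' means recomputed and the log-linear fit repeated.
#'
#' @param measurements per-cell measurement table.
#' @param compartment compartment to fit.
#' @param window fit window.
#' @param reps bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param channel,segments passed to [aggregateSeries()].
#' @return list with `halfLife`, `se`, `ci` (2.5/97.5 percentiles).
#' @export
bootstrapHalfLife <- function(measurements, compartment, window = NULL,
                              reps = 1000L, seed = 1L, channel = "gfp",
                              segments = NULL) {
  m <- measurements[measurements$compartment == compartment, , drop = FALSE]
  if ("channel" %in% names(m)) m <- m[m$channel == channel, , drop = FALSE]
  if (!is.null(segments) && "segment" %in% names(m))
    m <- m[m$segment %in% segments, , drop = FALSE]
  m <- m[!is.na(m$intensity), , drop = FALSE]
  percell <- stats::aggregate(intensity ~ cell_id + day, data = m, FUN = mean)
  cells <- unique(percell$cell_id)
  est <- halfLife(fitExponential(
    aggregateSeries(measurements, compartment, channel = channel,
                    segments = segments), window = window))
  bySplit <- split(percell, percell$cell_id)
  hl <- withSeed(seed, vapply(seq_len(reps), function(r) {
    take <- sample(cells, length(cells), replace = TRUE)
    sub <- do.call(rbind, bySplit[take])
    agg <- stats::aggregate(intensity ~ day, data = sub, FUN = mean)
    names(agg)[2L] <- "mean"
    tryCatch(halfLife(fitExponential(agg, window = window)),
             error = function(e) NA_real_)
  }, numeric(1)))
  hl <- hl[is.finite(hl)]
  list(halfLife = est, se = stats::sd(hl),
       ci = stats::quantile(hl, c(0.025, 0.975), names = FALSE))
}
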