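# Evaluation of compartment decay trajectories and the bleach model.

#' Days over which a kinetics object is defined
#'
#' @param kinetics a [CompartmentKinetics-class] object.
#' @return numeric(2), first and last day of the phase support.
#' @export
kineticsSupport <- function(kinetics) {
  ph <- kinetics@phases
  c(ph[1L, 1L], ph[nrow(ph), 2L])
}

# trajectory of the compartment-level N(t); continuity at breakpoints comes
# from seeding each phase with the value reached by the preceding one
trajectoryAt <- function(kinetics, day) {
  ph <- kinetics@phases
  sup <- kineticsSupport(kinetics)
  if (day < sup[1L] - 1e-9 || day > sup[2L] + 1e-9)
    stop("day outside kinetics support")
  n <- kinetics@N0
  for (i in seq_len(nrow(ph))) {
    if (day <= ph[i, 2L] + 1e-12)
      return(n * exp(-ph[i, 3L] * (day - ph[i, 1L])))
    n <- n * exp(-ph[i, 3L] * (ph[i, 2L] - ph[i, 1L]))
  }
  n
}

#' Evaluate a compartment trajectory
#'
#' Noise-free compartment mean intensity at a given day (the quantity a
#' noiseless rendered image reproduces). With per-bin decay coefficients the
#' compartment value is the mean of the five bin trajectories.
#'
#' @param kinetics a [CompartmentKinetics-class] object.
#' @param day day in culture; must fall inside the phase support.
#' @param bleach optional [BleachSpec-class]; when supplied the value
#'   returned is the one inside the bleached region.
#' @return intensity (a.u.).
#' @examples
#' k <- CompartmentKinetics("bundle", 1000, c(0, 5, log(2)))
#' compartmentIntensity(k, 1)  # one half-life -> 500
#' @export
compartmentIntensity <- function(kinetics, day, bleach = NULL) {
  mean(binIntensities(kinetics, day, bleach = bleach))
}

#' Per-bin bundle trajectories
#'
#' Five transverse-bin intensities (edge, interior, center, interior, edge)
#' at a given day. Without per-bin structure all five equal the compartment
#' trajectory.
#'
#' @inheritParams compartmentIntensity
#' @return named numeric(5).
#' @export
binIntensities <- function(kinetics, day, bleach = NULL) {
  st <- bleachState(kinetics, day, bleach)
  tEval <- st$dayEval
  sp <- if (length(kinetics@spatialProfile)) kinetics@spatialProfile else rep(1, 5)
  if (length(kinetics@binLambda)) {
    t0 <- kinetics@phases[1L, 1L]
    sup <- kineticsSupport(kinetics)
    if (tEval < sup[1L] - 1e-9 || tEval > sup[2L] + 1e-9)
      stop("day outside kinetics support")
    v <- kinetics@N0 * sp * exp(-kinetics@binLambda * (tEval - t0))
  } else {
    v <- trajectoryAt(kinetics, tEval) * sp
  }
  stats::setNames(v * st$factor, binNames)
}

# bleach semantics: before the bleach nothing changes; from the bleach to
# the recovery end-point the trajectory is scaled by (1 - efficiency); from
# the end-point on, the value is pinned to the pre-bleach (bleach-day) value
# times ((1 - efficiency) + recoveryFraction * efficiency)
bleachState <- function(kinetics, day, bleach) {
  if (is.null(bleach) || day < bleach@bleachDay)
    return(list(dayEval = day, factor = 1))
  eff <- bleach@efficiency
  if (day < bleach@bleachDay + bleach@recoveryDelayDays)
    return(list(dayEval = day, factor = 1 - eff))
  recov <- if (kinetics@compartment == "surround")
    bleach@surroundRecoveryFraction else bleach@bundleRecoveryFraction
  list(dayEval = bleach@bleachDay, factor = (1 - eff) + recov * eff)
}

#' Apply a photobleach to compartment trajectories
#'
#' Convenience wrapper returning bleached trajectory values for a set of
#' days; rendering applies the same model pixel-wise inside the bleached
#' region (see [applyBleach()] for image stacks).
#'
#' @param kinetics a [CompartmentKinetics-class] object.
#' @param days numeric vector of days.
#' @param bleach a [BleachSpec-class] object.
#' @return numeric vector of intensities inside the bleached region.
#' @export
bleachedTrajectory <- function(kinetics, days, bleach) {
  vapply(days, function(d) compartmentIntensity(kinetics, d, bleach = bleach),
         numeric(1))
}
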