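# Closed-form steady-state diffusion of a secreted enzyme in brain
# extracellular space: tortuosity-adjusted coefficient and relative
# concentration versus distance from a non-depleting source.
#
# Units: distances in um, rates in s^-1, diffusion coefficients supplied
# in cm^2/s and converted internally (1 cm^2/s = 1e8 um^2/s).

.CM2_TO_UM2 <- 1e8

#' Tortuosity-adjusted diffusion coefficient
#'
#' `D* = D / lambda^2`, where lambda is the tortuosity of brain
#' extracellular space. For a 60 kDa carboxylesterase, D = 4.3e-7 cm^2/s
#' in free solution and lambda = 2.25 (characteristic of high molecular
#' weight molecules in brain) give D* = 8.5e-8 cm^2/s.
#'
#' @param dFreeCm2S free-solution diffusion coefficient, cm^2/s (> 0).
#' @param lambdaTortuosity tortuosity lambda >= 1 (1 = free solution).
#' @return D* in cm^2/s.
#' @examples
#' signif(effectiveDiffusion(4.3e-7, 2.25), 2)   # 8.5e-08
#' @export
effectiveDiffusion <- function(dFreeCm2S, lambdaTortuosity) {
  if (dFreeCm2S <= 0) stop("'dFreeCm2S' must be positive")
  if (lambdaTortuosity < 1)
    stop("'lambdaTortuosity' below 1 is unphysical in tissue")
  dFreeCm2S / lambdaTortuosity^2
}

#' Elimination rate from half-life
#'
#' `ke = ln(2) / tHalf`.
#'
#' @param tHalfS half-life in seconds (> 0).
#' @return elimination rate constant, s^-1.
#' @examples
#' keFromHalfLife(log(2))   # 1
#' @export
keFromHalfLife <- function(tHalfS) {
  if (tHalfS <= 0) stop("'tHalfS' must be positive")
  log(2) / tHalfS
}

#' Steady-state relative concentration at distance x
#'
#' `C/C0 = exp(-x * sqrt(ke / D*))` for a non-depleting source with
#' first-order elimination. At x = 0, or with ke = 0 (no elimination),
#' the ratio is 1. The elimination rate has no default — it must be
#' supplied or derived from a half-life via [keFromHalfLife()].
#'
#' @param xUm distance from the source in um (>= 0; vectorized).
#' @param kePerS elimination rate constant, s^-1 (>= 0).
#' @param dStarCm2S tortuosity-adjusted diffusion coefficient, cm^2/s.
#' @return C/C0 in (0, 1].
#' @examples
#' ke <- (log(2) / 25)^2 * 8.5   # rate putting the half-distance at 25 um
#' relativeConcentration(c(0, 25, 50), ke, 8.5e-8)   # 1, 0.5, 0.25
#' @export
relativeConcentration <- function(xUm, kePerS, dStarCm2S) {
  if (any(xUm < 0)) stop("'xUm' must be non-negative")
  if (kePerS < 0) stop("'kePerS' must be non-negative")
  if (dStarCm2S <= 0) stop("'dStarCm2S' must be positive")
  exp(-xUm * sqrt(kePerS / (dStarCm2S * .CM2_TO_UM2)))
}

#' Distance at which concentration falls to a given fraction
#'
#' Inverse of [relativeConcentration()]:
#' `x = -ln(fraction) / sqrt(ke / D*)`.
#'
#' @param fraction target C/C0 in (0, 1].
#' @param kePerS elimination rate constant, s^-1 (> 0).
#' @param dStarCm2S tortuosity-adjusted diffusion coefficient, cm^2/s.
#' @return distance in um.
#' @export
distanceForFraction <- function(fraction, kePerS, dStarCm2S) {
  if (any(fraction <= 0) || any(fraction > 1))
    stop("'fraction' must lie in (0, 1]")
  if (kePerS <= 0) stop("'kePerS' must be positive")
  if (dStarCm2S <= 0) stop("'dStarCm2S' must be positive")
  -log(fraction) / sqrt(kePerS / (dStarCm2S * .CM2_TO_UM2))
}

#' Concentration-distance profile
#'
#' Evaluates the steady-state profile on a distance grid, for export or
#' plotting.
#'
#' @param distancesUm distance grid in um.
#' @param kePerS elimination rate constant, s^-1.
#' @param dStarCm2S tortuosity-adjusted diffusion coefficient, cm^2/s.
#' @param file optional CSV path to write the profile to.
#' @return data.frame with `distance_um` and `relative_concentration`.
#' @export
concentrationProfile <- function(distancesUm = seq(0, 100, by = 1), kePerS,
                                 dStarCm2S, file = NULL) {
  prof <- data.frame(
    distance_um = distancesUm,
    relative_concentration = relativeConcentration(distancesUm, kePerS,
                                                   dStarCm2S)
  )
  if (!is.null(file)) utils::write.csv(prof, file, row.names = FALSE)
  prof
}
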