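#' Frequency-mean specific energy of a spherical water target
#'
#' For a single charged-particle traversal of a water sphere of diameter `d`
#' (micrometres) with linear energy transfer `let` (keV/um), the
#' frequency-mean specific energy is `0.204 * let / d^2` gray. The constant
#' 0.204 carries the unit conversion keV/um and um to Gy for unit-density
#' water.
#'
#' @param let Unrestricted LET in keV/um (>= 0).
#' @param diameter_um Target diameter in micrometres (> 0).
#' @return Specific energy per event, in Gy.
#' @examples
#' frequency_mean_specific_energy(6.6, 8)  # ~0.0210 Gy
#' @export
frequency_mean_specific_energy <- function(let, diameter_um = 8) {
  if (any(let < 0)) stop("let must be >= 0")
  if (diameter_um <= 0) stop("diameter_um must be > 0")
  0.204 * let / diameter_um^2
}

#' Secondary-electron fluence spectrum
#'
#' Container for (energy, fluence, LET) triples describing the
#' energy-fluence density of secondary electrons, the weighting used in
#' fluence-averaged yield calculations. Energies must be strictly
#' increasing; fluence is a relative density (any uniform rescaling leaves
#' weighted yields unchanged).
#'
#' @param energy_kev Strictly increasing electron energies, keV.
#' @param fluence Non-negative relative energy-fluence densities; at least
#'   one must be positive.
#' @param let_kev_um Non-negative unrestricted LET values, keV/um.
#' @return A `fluence_spectrum` data frame.
#' @export
fluence_spectrum <- function(energy_kev, fluence, let_kev_um) {
  if (length(energy_kev) == 0L) stop("spectrum needs at least one point")
  if (any(diff(energy_kev) <= 0)) stop("energies must be strictly increasing")
  if (any(energy_kev <= 0)) stop("energies must be positive")
  if (any(fluence < 0) || any(let_kev_um < 0)) {
    stop("fluence and LET must be >= 0")
  }
  if (!any(fluence > 0)) stop("at least one point must have fluence > 0")
  structure(data.frame(energy_kev = energy_kev, fluence = fluence,
                       let_kev_um = let_kev_um),
            class = c("fluence_spectrum", "data.frame"))
}

#' Energy-dependent yield curve
#'
#' Tabulated damage yield (per Gy per Gbp) as a function of electron energy,
#' interpolated log-linearly in energy when evaluated between nodes.
#' Evaluation outside the tabulated range is an error: low-energy behaviour
#' dominates the bias budget, so silent extrapolation is forbidden.
#'
#' @param energy_kev Strictly increasing energies, keV.
#' @param yield Non-negative yields per Gy per Gbp.
#' @return A `yield_curve` data frame.
#' @export
yield_curve <- function(energy_kev, yield) {
  if (length(energy_kev) == 0L) stop("curve needs at least one point")
  if (any(diff(energy_kev) <= 0)) stop("energies must be strictly increasing")
  if (any(energy_kev <= 0)) stop("energies must be positive")
  if (any(yield < 0)) stop("yields must be >= 0")
  structure(data.frame(energy_kev = energy_kev, yield = yield),
            class = c("yield_curve", "data.frame"))
}

eval_yield_curve <- function(curve, energy) {
  rng <- range(curve$energy_kev)
  if (any(energy < rng[1] - 1e-12) || any(energy > rng[2] + 1e-12)) {
    stop(sprintf(paste0("yield curve evaluated outside its tabulated range ",
                        "[%g, %g] keV; extrapolation is not allowed"),
                 rng[1], rng[2]))
  }
  if (nrow(curve) == 1L) return(rep(curve$yield, length(energy)))
  stats::approx(log(curve$energy_kev), curve$yield, xout = log(energy),
                rule = 1)$y
}

#' Fluence/LET-weighted damage yield
#'
#' Dose-weighted mean of a yield curve over a secondary-electron fluence
#' spectrum: `Y = int Y(E) Phi(E) LET(E) dE / int Phi(E) LET(E) dE`. The
#' quadrature is trapezoidal on the union of the curve and spectrum energy
#' grids (restricted to their overlap), with the yield interpolated
#' log-linearly in energy and the weight `Phi * LET` linearly. A
#' single-point spectrum reduces to `Y(E0)`.
#'
#' @param curve A [yield_curve()].
#' @param spectrum A [fluence_spectrum()]. Every point with positive fluence
#'   must lie inside the curve's tabulated energy range.
#' @return The weighted yield, per Gy per Gbp.
#' @export
dose_weighted_yield <- function(curve, spectrum) {
  stopifnot(inherits(curve, "yield_curve"),
            inherits(spectrum, "fluence_spectrum"))
  sup <- spectrum[spectrum$fluence > 0, , drop = FALSE]
  rng <- range(curve$energy_kev)
  if (min(sup$energy_kev) > rng[2] || max(sup$energy_kev) < rng[1]) {
    stop("no energy overlap between yield curve and fluence spectrum")
  }
  if (nrow(sup) == 1L) {
    return(eval_yield_curve(curve, sup$energy_kev))
  }
  grid <- sort(unique(c(curve$energy_kev, sup$energy_kev)))
  grid <- grid[grid >= min(sup$energy_kev) & grid <= max(sup$energy_kev)]
  w <- stats::approx(sup$energy_kev, sup$fluence * sup$let_kev_um,
                     xout = grid, rule = 1)$y
  y <- eval_yield_curve(curve, grid)
  dx <- diff(grid)
  num <- sum(dx * (w[-1] * y[-1] + w[-length(w)] * y[-length(y)]) / 2)
  den <- sum(dx * (w[-1] + w[-length(w)]) / 2)
  if (den <= 0) stop("denominator integral is zero: spectrum carries no weight")
  num / den
}
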