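#' Stokes radius predicted from molecular mass
#'
#' Empirical power law for compact globular proteins:
#' `log10(Rs[A]) = -0.254 + 0.369 log10(MW[Da])`, returned in nm. The
#' regression coefficients are used at their central values; their
#' uncertainties are not propagated.
#'
#' @param mw molecular mass(es) in Da, > 0.
#' @return Stokes radius in nm.
#' @export
rs_from_mw <- function(mw) {
  if (any(mw <= 0)) stop("'mw' must be positive")
  10^(-0.254 + 0.369 * log10(mw)) / 10
}

#' Percent polydispersity of a size distribution
#'
#' `%Pd = 100 * sd / mean` where both moments are weighted by the supplied
#' mass fractions (population, not sample, standard deviation). Weights
#' that do not sum to 1 within 1e-6 are renormalized with a warning.
#'
#' @param rs_values hydrodynamic radii (any consistent unit).
#' @param weights mass fractions; default equal.
#' @return Percent polydispersity (scale-invariant).
#' @export
polydispersity_percent <- function(rs_values, weights = NULL) {
  n <- length(rs_values)
  if (n == 0L) stop("empty size distribution")
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n) stop("'weights' must match 'rs_values'")
  if (any(weights < 0)) stop("'weights' must be non-negative")
  if (abs(sum(weights) - 1) > 1e-6) {
    warning("mass fractions do not sum to 1; renormalizing")
  }
  w <- weights / sum(weights)
  mu <- sum(w * rs_values)
  100 * sqrt(sum(w * (rs_values - mu)^2)) / mu
}

#' Molecular mass from the Svedberg equation
#'
#' `M = s0 R T / (D0 (1 - vbar rho))` with s0 the sedimentation
#' coefficient at infinite dilution (Svedberg, 1e-13 s), D0 the diffusion
#' coefficient (cm^2/s), vbar the partial specific volume (mL/g) and rho
#' the solvent density (g/mL); R in cgs units.
#'
#' @param s0 sedimentation coefficient, Svedberg.
#' @param D0 diffusion coefficient, cm^2/s.
#' @param vbar partial specific volume, mL/g (default 0.73).
#' @param rho solvent density, g/mL (default 1.0).
#' @param temperature_K temperature, K (default 293.15).
#' @return Molecular mass in Da.
#' @export
svedberg_mass <- function(s0, D0, vbar = 0.73, rho = 1.0,
                          temperature_K = 293.15) {
  stopifnot(s0 > 0, D0 > 0, vbar > 0, rho > 0, temperature_K > 0)
  buoy <- 1 - vbar * rho
  if (buoy <= 0)
    stop("vbar * rho >= 1: buoyancy term vanishes, mass undetermined")
  R_cgs <- 8.31446e7  # erg mol-1 K-1
  (s0 * 1e-13) * R_cgs * temperature_K / (D0 * buoy)
}

#' Stokes radius from the Stokes-Einstein relation
#'
#' `Rs = kB T / (6 pi eta D0)` with eta the solvent viscosity in poise and
#' D0 in cm^2/s; returned in nm.
#'
#' @param D0 diffusion coefficient, cm^2/s.
#' @param eta solvent viscosity, poise (default 0.01002, water at 20 C).
#' @param temperature_K temperature, K (default 293.15).
#' @return Stokes radius in nm.
#' @export
stokes_einstein_rs <- function(D0, eta = 0.01002, temperature_K = 293.15) {
  stopifnot(D0 > 0, eta > 0, temperature_K > 0)
  kB_cgs <- 1.380649e-16  # erg / K
  rs_cm <- kB_cgs * temperature_K / (6 * pi * eta * D0)
  rs_cm * 1e7
}
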