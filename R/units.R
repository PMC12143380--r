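# Unit conventions used throughout the package:
#   * energies and frequencies are quoted in wavenumbers (cm^-1)
#   * time is quoted in femtoseconds (fs)
#   * internally, dynamics works in "angular" units where hbar = 1 and an
#     energy E [cm^-1] becomes an angular frequency 2*pi*c*E [rad/fs]
# Mass-scaled nuclear coordinates are used, so the bath Hamiltonian is
# p^2/2 + omega^2 q^2 / 2 with omega in rad/fs.

#' Physical constants in spectroscopic units
#'
#' Speed of light in cm/fs and the Boltzmann constant in cm^-1/K, the two
#' constants that fix the package's unit system.
#'
#' @format Named numeric values.
#' @name constants
NULL

# speed of light in cm/fs
.c_cm_fs <- 2.99792458e-5

# Boltzmann constant in cm^-1 / K (so kT at 300 K is about 208.5 cm^-1)
.kB_cm1 <- 0.69503476

#' Convert a wavenumber to an angular frequency
#'
#' @param nu_cm1 Wavenumber(s) in cm^-1.
#' @return Angular frequency in rad/fs.
#' @examples
#' cm1_to_radfs(1000)  # about 0.188 rad/fs
#' @export
cm1_to_radfs <- function(nu_cm1) 2 * pi * .c_cm_fs * nu_cm1

#' Convert an angular frequency back to a wavenumber
#'
#' @param omega_radfs Angular frequency in rad/fs.
#' @return Wavenumber in cm^-1.
#' @export
radfs_to_cm1 <- function(omega_radfs) omega_radfs / (2 * pi * .c_cm_fs)

#' Thermal energy in wavenumbers
#'
#' @param temperature Temperature in kelvin.
#' @return k_B T in cm^-1.
#' @examples
#' thermal_energy_cm1(300)
#' @export
thermal_energy_cm1 <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  .kB_cm1 * temperature
}

# coth(beta hbar omega / 2) with both energies in cm^-1; equals 2 n(omega) + 1
# where n is the Bose-Einstein occupation.
.coth_half_beta <- function(omega_cm1, temperature) {
  x <- omega_cm1 / (2 * .kB_cm1 * temperature)
  1 / tanh(x)
}

# run expr with a local, restartable RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
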