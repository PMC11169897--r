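#' Physical constants used throughout the package
#'
#' SI values (CODATA). Exposed as a list so that every module draws the same
#' numbers; cross-section work is done in nm^2, wavelengths in nm, current
#' densities in A/m^2, incident intensities in mW/mm^2 (1 mW/mm^2 = 1000 W/m^2).
#'
#' @format A named list:
#' \describe{
#'   \item{q}{elementary charge, C}
#'   \item{h}{Planck constant, J s}
#'   \item{c0}{speed of light in vacuum, m/s}
#'   \item{hc}{h * c0, J m}
#'   \item{N_A}{Avogadro constant, 1/mol}
#'   \item{kB}{Boltzmann constant, J/K}
#'   \item{eV_nm}{photon energy-wavelength product, eV nm (E = eV_nm / lambda)}
#'   \item{silver_atom_density_nm3}{bulk silver atomic density, atoms/nm^3}
#' }
#' @export
pv_constants <- list(
  q    = 1.602176634e-19,
  h    = 6.62607015e-34,
  c0   = 2.99792458e8,
  hc   = 6.62607015e-34 * 2.99792458e8,
  N_A  = 6.02214076e23,
  kB   = 1.380649e-23,
  eV_nm = 1239.841984,
  # 10.49 g/cm^3 / 107.8682 g/mol * N_A = 5.856e22 cm^-3
  silver_atom_density_nm3 = 10.49 / 107.8682 * 6.02214076e23 * 1e-21
)

#' Convert incident intensity from mW/mm^2 to W/m^2
#' @param intensity_mW_mm2 intensity in mW/mm^2
#' @return intensity in W/m^2
#' @export
intensity_W_m2 <- function(intensity_mW_mm2) intensity_mW_mm2 * 1000

#' Absorption coefficient from the extinction index
#'
#' alpha(lambda) = 4 * pi * k / lambda.
#'
#' @param k extinction index (dimensionless, >= 0)
#' @param wavelength_nm wavelength in nm
#' @return absorption coefficient in 1/m
#' @export
absorption_coefficient <- function(k, wavelength_nm) {
  stopifnot(all(k >= 0), all(wavelength_nm > 0))
  4 * pi * k / (wavelength_nm * 1e-9)
}
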