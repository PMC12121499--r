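#' Physical constants used throughout the package
#'
#' Fixed (CODATA-derived) constants for unit conversion and rate theory.
#' All internal energies are electron-volts; wavenumbers and nanometres
#' appear only at input/output boundaries.
#'
#' @format A named list:
#' \describe{
#'   \item{cm1_per_ev}{wavenumbers per eV, 8065.544 cm^-1/eV}
#'   \item{hc_ev_nm}{hc, 1239.84193 eV nm}
#'   \item{k_boltzmann_ev}{Boltzmann constant, 8.61733e-5 eV/K}
#'   \item{hbar_ev_s}{reduced Planck constant, 6.58212e-16 eV s}
#'   \item{dipole_coupling_prefactor}{5034.1; converts Debye^2/Angstrom^3 to cm^-1
#'     in the point-dipole coupling}
#'   \item{oscillator_prefactor}{4.702e-7; dimensionless oscillator strength per
#'     (cm^-1 Debye^2)}
#' }
#' @export
frl_constants <- list(
  cm1_per_ev = 8065.544,
  hc_ev_nm = 1239.84193,
  k_boltzmann_ev = 8.61733e-5,
  hbar_ev_s = 6.58212e-16,
  dipole_coupling_prefactor = 5034.1,
  oscillator_prefactor = 4.702e-7,
  constants_version = "codata-2018-fixed"
)

#' Convert photon energy to wavelength
#'
#' `ev_to_nm()` maps energies in eV to vacuum wavelengths in nm via
#' lambda = hc / E with hc = 1239.84193 eV nm; `nm_to_ev()` is its inverse.
#'
#' @param energy_ev Photon energy in eV, positive.
#' @return Wavelength in nm.
#' @examples
#' ev_to_nm(1.840)   # ~ 674 nm
#' nm_to_ev(701)     # ~ 1.769 eV
#' @export
ev_to_nm <- function(energy_ev) {
  if (any(!is.finite(energy_ev)) || any(energy_ev <= 0)) {
    stop("ev_to_nm(): energy must be positive and finite")
  }
  frl_constants$hc_ev_nm / energy_ev
}

#' @rdname ev_to_nm
#' @param wavelength_nm Wavelength in nm, positive.
#' @export
nm_to_ev <- function(wavelength_nm) {
  if (any(!is.finite(wavelength_nm)) || any(wavelength_nm <= 0)) {
    stop("nm_to_ev(): wavelength must be positive and finite")
  }
  frl_constants$hc_ev_nm / wavelength_nm
}

#' Reporting helpers: wavelengths as integers, energies to 3 decimals
#'
#' Matches the conventional reporting style for Q-band positions
#' (e.g. "1.769 eV / 701 nm").
#'
#' @param energy_ev energy in eV
#' @return `report_nm()`: integer nm; `report_ev()`: eV rounded to 3 decimals.
#' @export
report_nm <- function(energy_ev) as.integer(round(ev_to_nm(energy_ev)))

#' @rdname report_nm
#' @export
report_ev <- function(energy_ev) round(energy_ev, 3)

#' Convert between wavenumbers and eV
#'
#' Uses 1 eV = 8065.544 cm^-1.
#'
#' @param x numeric vector to convert.
#' @return converted numeric vector.
#' @export
cm1_to_ev <- function(x) x / frl_constants$cm1_per_ev

#' @rdname cm1_to_ev
#' @export
ev_to_cm1 <- function(x) x * frl_constants$cm1_per_ev
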