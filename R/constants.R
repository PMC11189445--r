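## Physical constants used across the package.  Energies are kept in
## kcal/mol and lengths in Angstrom throughout.

#' Physical constants
#'
#' Constants used by the simulation and free-energy code: the gas constant
#' in kcal mol^-1 K^-1, the elementary charge in coulomb, and the
#' conversion from electronvolt to kcal/mol.
#'
#' @format Named numeric vector.
#' @export
pk_constants <- c(
  R_kcal    = 1.9872e-3,        # gas constant, kcal mol^-1 K^-1
  e_coulomb = 1.602176634e-19,  # elementary charge, C
  eV_kcal   = 23.060548         # 1 eV in kcal/mol
)

#' Thermal energy kT in kcal/mol
#'
#' @param temperature Temperature in kelvin (default 298 K).
#' @return kT in kcal/mol (0.5922 at 298 K).
#' @examples
#' kT_kcal(298)
#' @export
kT_kcal <- function(temperature = 298) {
  pk_constants[["R_kcal"]] * temperature
}

#' Membrane-voltage energy for a monovalent cation
#'
#' Converts a transmembrane voltage into the potential-energy drop
#' experienced by a +1e ion across the membrane span, in kcal/mol.
#' 500 mV corresponds to 11.53 kcal/mol.
#'
#' @param voltage_mV Voltage in millivolt (signed).
#' @param charge Ion charge in units of e (default +1 for K+).
#' @return Energy in kcal/mol (signed).
#' @export
voltage_energy_kcal <- function(voltage_mV, charge = 1) {
  charge * (voltage_mV / 1000) * pk_constants[["eV_kcal"]]
}

## Standard atomic masses (u) for centre-of-mass computations.
.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  K = 39.098, NA. = 22.990, CL = 35.45, MG = 24.305, CA. = 40.078,
  ZN = 65.38, FE = 55.845, SE = 78.971
)

atomic_mass <- function(element) {
  el <- toupper(element)
  el[el == "NA"] <- "NA."
  el[el == "CA"] <- "CA."
  m <- .atomic_masses[el]
  if (anyNA(m)) {
    warning("unknown element(s) ", paste(unique(element[is.na(m)]), collapse = ", "),
            "; using mass 12")
    m[is.na(m)] <- 12
  }
  unname(m)
}
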