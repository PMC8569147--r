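#' Physical constants and unit conversions used throughout the package
#'
#' Units are Angstrom, kcal/mol, ps (velocities in Angstrom/ps), K and atm.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, kcal mol^-1 K^-1.}
#'   \item{atmA3_to_kcal}{1 atm * Angstrom^3 in kcal/mol (barostat work term).}
#'   \item{hartree_to_kcal}{1 Hartree in kcal/mol.}
#'   \item{coulomb}{Coulomb prefactor, kcal Angstrom mol^-1 e^-2.}
#'   \item{mass_O, mass_H}{atomic masses, amu.}
#'   \item{molar_mass_water}{g/mol.}
#'   \item{avogadro}{Avogadro constant, mol^-1.}
#'   \item{kcal_per_amuA2ps2}{1 amu Angstrom^2 ps^-2 in kcal/mol.}
#'   \item{debye_to_eA}{1 Debye in e * Angstrom.}
#' }
#' @export
mbpef_constants <- list(
  kB = 0.0019872041,
  atmA3_to_kcal = 1.4584e-5,
  hartree_to_kcal = 627.509474,
  coulomb = 332.0637157,
  mass_O = 15.999,
  mass_H = 1.008,
  molar_mass_water = 18.01528,
  avogadro = 6.02214076e23,
  kcal_per_amuA2ps2 = 1 / 418.4,
  debye_to_eA = 0.2081943
)
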