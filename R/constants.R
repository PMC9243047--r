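## Physical constants (CODATA 2018, exact SI where defined) and element data.
## All unit conversions in the package flow through this table.

#' Physical constants used throughout the package
#'
#' A single pinned table of CODATA-2018 constants.  Energies are handled in
#' kcal/mol internally; wavenumbers stay in cm^-1; coordinates in Angstrom.
#'
#' @format A named list:
#' \describe{
#'   \item{kB}{Boltzmann constant, J/K}
#'   \item{NA}{Avogadro constant, 1/mol}
#'   \item{h}{Planck constant, J s}
#'   \item{c}{speed of light, cm/s}
#'   \item{cal}{thermochemical calorie, J}
#'   \item{amu}{atomic mass unit, kg}
#'   \item{atm}{standard atmosphere, Pa}
#'   \item{R_kcal}{gas constant, kcal/(mol K)}
#'   \item{R_cal}{gas constant, cal/(mol K)}
#'   \item{hartree_kcal}{hartree to kcal/mol conversion}
#'   \item{wavenumber_kcal}{kcal/mol per cm^-1 (h c NA / cal / 1000)}
#' }
#' @export
PHYS_CONST <- local({
  kB   <- 1.380649e-23
  NAv  <- 6.02214076e23
  h    <- 6.62607015e-34
  c_cm <- 2.99792458e10
  cal  <- 4.184
  list(
    kB   = kB,
    "NA" = NAv,
    h    = h,
    c    = c_cm,
    cal  = cal,
    amu  = 1.66053906660e-27,
    atm  = 101325,
    R_kcal = kB * NAv / (cal * 1000),
    R_cal  = kB * NAv / cal,
    hartree_kcal = 627.5095,
    wavenumber_kcal = h * c_cm * NAv / (cal * 1000)
  )
})

## Average atomic masses (amu) for the elements this package handles.
.ATOMIC_MASS <- c(
  H = 1.008, He = 4.002602, Li = 6.94, Be = 9.0121831, B = 10.81,
  C = 12.011, N = 14.007, O = 15.999, F = 18.998403163, Ne = 20.1797,
  Na = 22.98976928, Mg = 24.305, Al = 26.9815385, Si = 28.085,
  P = 30.973761998, S = 32.06, Cl = 35.45, Ar = 39.948, K = 39.0983,
  Ca = 40.078
)

## Covalent radii (Angstrom), Cordero et al. consensus values.
.COVALENT_RADIUS <- c(
  H = 0.31, He = 0.28, Li = 1.28, Be = 0.96, B = 0.84,
  C = 0.76, N = 0.71, O = 0.66, F = 0.57, Ne = 0.58,
  Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11,
  P = 1.07, S = 1.05, Cl = 1.02, Ar = 1.06, K = 2.03, Ca = 1.76
)

#' Atomic masses of the atoms of a geometry
#' @param elements character vector of element symbols
#' @return numeric vector of masses in amu
#' @keywords internal
atomic_masses <- function(elements) {
  m <- .ATOMIC_MASS[elements]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(elements[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' Thermal energy kB*T per mole
#'
#' @param T temperature in kelvin (vectorized, T >= 0)
#' @return kB*T*NA in kcal/mol
#' @examples
#' thermal_energy_kT(298.15) # ~0.59 kcal/mol
#' thermal_energy_kT(343)    # ~0.68, i.e. 0.7 at one decimal
#' @export
thermal_energy_kT <- function(T) {
  stopifnot(all(T >= 0))
  PHYS_CONST$R_kcal * T
}
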