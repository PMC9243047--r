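## Rigid-rotor / harmonic-oscillator (RRHO) ideal-gas thermochemistry.
## Energies in kcal/mol, entropies in cal/(mol K); standard state is the
## ideal gas at the stated temperature and pressure (no solution-phase
## standard-state correction is applied for either phase tag).

#' Thermodynamic conditions
#'
#' @param T temperature, kelvin (default 298.15)
#' @param P pressure, atm (default 1)
#' @return a `thermo_conditions`
#' @export
thermo_conditions <- function(T = 298.15, P = 1) {
  stopifnot(T > 0, P > 0)
  structure(list(T = T, P = P), class = "thermo_conditions")
}

#' Zero-point vibrational energy
#'
#' ZPE = 1/2 sum h c nu_i per mole, over real harmonic wavenumbers.
#'
#' @param frequencies wavenumbers in cm^-1, all > 0
#' @return ZPE in kcal/mol
#' @export
zpe_from_frequencies <- function(frequencies) {
  if (!length(frequencies)) return(0)
  if (any(frequencies <= 0)) {
    stop("not a minimum: imaginary or zero frequency passed to ZPE")
  }
  0.5 * sum(frequencies) * PHYS_CONST$wavenumber_kcal
}

#' RRHO thermochemistry of one structure
#'
#' Translational terms from the ideal gas (Sackur-Tetrode entropy),
#' rotational terms from the classical rigid rotor (linear vs nonlinear top
#' detected from the principal moments of inertia), vibrational terms from
#' harmonic-oscillator partition functions.  All components refer to the
#' corrections beyond the electronic energy.
#'
#' @param geom a non-empty `geometry` (masses and moments come from it)
#' @param frequencies harmonic wavenumbers in cm^-1 (all > 0); must be
#'   empty for a single atom
#' @param conditions a [thermo_conditions()]
#' @param sigma rotational symmetry number (default 1; the nucleoside-scale
#'   molecules this package targets are asymmetric)
#' @return a `thermo_breakdown`: list with `zpe`, `h_thermal` (thermal
#'   correction to enthalpy beyond ZPE), `s_trans`, `s_rot`, `s_vib`
#'   (cal/(mol K)), `H`, `S`, `G` (enthalpy/Gibbs in kcal/mol, entropy in
#'   cal/(mol K)); `G = H - T S` holds to within 1e-9
#' @export
rrho_thermo <- function(geom, frequencies = numeric(0),
                        conditions = thermo_conditions(), sigma = 1) {
  n <- n_atoms(geom)
  if (!n) stop("empty geometry")
  if (n == 1 && length(frequencies)) {
    stop("inconsistent input: a single atom has no vibrational modes")
  }
  if (any(frequencies <= 0)) {
    stop("not a minimum: imaginary or zero frequency")
  }
  T <- conditions$T; P <- conditions$P
  kB <- PHYS_CONST$kB; h <- PHYS_CONST$h; NAv <- PHYS_CONST$`NA`
  R_cal <- PHYS_CONST$R_cal; R_kcal <- PHYS_CONST$R_kcal

  ## translation (Sackur-Tetrode)
  m_kg <- sum(atomic_masses(geom$elements)) * PHYS_CONST$amu
  P_pa <- P * PHYS_CONST$atm
  q_t <- (2 * pi * m_kg * kB * T / h^2)^1.5 * (kB * T / P_pa)
  s_trans <- R_cal * (log(q_t) + 2.5)
  e_trans <- 1.5 * R_kcal * T

  ## rotation
  if (n == 1) {
    s_rot <- 0; e_rot <- 0
  } else {
    pm <- principal_moments(geom) * PHYS_CONST$amu * 1e-20 # kg m^2
    if (is_linear_geometry(geom)) {
      I <- pm[3]
      theta <- h^2 / (8 * pi^2 * I * kB)
      q_r <- T / (sigma * theta)
      s_rot <- R_cal * (log(q_r) + 1)
      e_rot <- R_kcal * T
    } else {
      theta <- h^2 / (8 * pi^2 * pm * kB)
      q_r <- sqrt(pi) / sigma * sqrt(T^3 / prod(theta))
      s_rot <- R_cal * (log(q_r) + 1.5)
      e_rot <- 1.5 * R_kcal * T
    }
  }

  ## vibration
  zpe <- zpe_from_frequencies(frequencies)
  if (length(frequencies)) {
    x <- frequencies * PHYS_CONST$wavenumber_kcal / (R_kcal * T)
    e_vib <- R_kcal * T * sum(x / expm1(x))
    s_vib <- R_cal * sum(x / expm1(x) - log(-expm1(-x)))
  } else {
    e_vib <- 0; s_vib <- 0
  }

  H <- zpe + e_trans + e_rot + e_vib + R_kcal * T # +RT: H = U + PV
  S <- s_trans + s_rot + s_vib
  G <- H - T * S / 1000
  structure(list(zpe = zpe, h_thermal = H - zpe,
                 s_trans = s_trans, s_rot = s_rot, s_vib = s_vib,
                 H = H, S = S, G = G, T = T, P = P),
            class = "thermo_breakdown")
}

#' @export
print.thermo_breakdown <- function(x, ...) {
  cat(sprintf(
    paste0("<thermo_breakdown> T = %.2f K, P = %.3g atm\n",
           "  ZPE = %.4f kcal/mol, H = %.4f kcal/mol\n",
           "  S = %.4f cal/(mol K) [trans %.2f, rot %.2f, vib %.2f]\n",
           "  G = %.4f kcal/mol\n"),
    x$T, x$P, x$zpe, x$H, x$S, x$s_trans, x$s_rot, x$s_vib, x$G))
  invisible(x)
}

#' Complete an energy record with RRHO thermochemistry
#'
#' @param geom the structure the record refers to
#' @param record an `energy_record` with real frequencies
#' @param conditions a [thermo_conditions()]
#' @param sigma rotational symmetry number
#' @return the record with `zpe`, `e_zpe` and `gibbs` filled in
#'   (G = E + G_corr)
#' @export
complete_energy_record <- function(geom, record,
                                   conditions = thermo_conditions(),
                                   sigma = 1) {
  if (!record$is_minimum) {
    stop("not a minimum: record has imaginary frequencies")
  }
  tb <- rrho_thermo(geom, record$frequencies, conditions, sigma)
  record$zpe <- tb$zpe
  record$e_zpe <- record$energy + tb$zpe
  record$gibbs <- record$energy + tb$G
  record
}
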