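## Physical constants (CODATA 2018, exact where the SI defines them).

#' Physical constants used throughout the package
#'
#' All unit conversions in the package funnel through this one table so that
#' every reported MV/cm, kcal/mol and s^-1 value is traceable to CODATA.
#'
#' @format A named list:
#' \describe{
#'   \item{e_C}{elementary charge, C (exact)}
#'   \item{kB_J_per_K}{Boltzmann constant, J/K (exact)}
#'   \item{h_J_s}{Planck constant, J s (exact)}
#'   \item{NA_per_mol}{Avogadro constant, 1/mol (exact)}
#'   \item{eps0_F_per_m}{vacuum permittivity, F/m}
#'   \item{R_kcal}{molar gas constant, kcal/(mol K)}
#'   \item{coulomb_MV_cm}{field of one elementary charge at 1 Angstrom,
#'     MV/cm; the single constant converting an e/A^2 Coulomb sum to MV/cm}
#'   \item{debye_MV_cm_kcal}{energy of a 1 D dipole in a 1 MV/cm field,
#'     kcal/mol; converts (D x MV/cm) Stark terms to kcal/mol}
#' }
#'
#' @details
#' `coulomb_MV_cm` is e/(4 pi eps0 r^2) evaluated at r = 1e-10 m and
#' converted from V/m to MV/cm (1 MV/cm = 1e8 V/m):
#' 8.9875517873681764e9 * 1.602176634e-19 / 1e-20 / 1e8 = 1439.9645...
#'
#' `debye_MV_cm_kcal` is (1e-21/c m^2 C) * 1e8 V/m * NA / 4184 J/kcal,
#' with the Debye defined as 1e-21/299792458 C m.
#'
#' @export
#' @examples
#' fc_constants$coulomb_MV_cm  # ~1439.96
fc_constants <- local({
  e    <- 1.602176634e-19
  kB   <- 1.380649e-23
  h    <- 6.62607015e-34
  NAv  <- 6.02214076e23
  c0   <- 299792458
  eps0 <- 8.8541878128e-12
  ke   <- 1 / (4 * pi * eps0)                 # 8.9875517873681764e9 N m^2 C^-2
  debye_Cm <- 1e-21 / c0                       # 3.33564095198e-30 C m
  list(
    e_C             = e,
    kB_J_per_K      = kB,
    h_J_s           = h,
    NA_per_mol      = NAv,
    eps0_F_per_m    = eps0,
    R_kcal          = kB * NAv / 4184,         # 1.987204259e-3 kcal/mol/K
    coulomb_MV_cm   = ke * e / 1e-20 / 1e8,    # 1439.964548 MV/cm per e/A^2
    debye_MV_cm_kcal = debye_Cm * 1e8 * NAv / 4184  # 0.04801 kcal/mol per D MV/cm
  )
})
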