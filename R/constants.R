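#' Physical constants in the package unit system
#'
#' The package works throughout in molecular-dynamics units: energy in
#' kJ/mol, time in fs, length in nm, charge in elementary charges (e),
#' dipole in e nm, electric field in kJ mol^-1 e^-1 nm^-1 and mass in amu.
#' In this system the reduced Planck constant is
#' \eqn{\hbar = 63.5078} kJ mol^-1 fs and the Boltzmann constant is
#' \eqn{k_B = 8.31446 \times 10^{-3}} kJ mol^-1 K^-1.
#'
#' `pmm_constants()` returns them all, mostly for documentation and for
#' unit-conversion checks in downstream scripts.
#'
#' @return Named list of constants (see Details).
#' @examples
#' pmm_constants()$hbar
#' @export
pmm_constants <- function() {
  list(
    hbar        = .hbar,         # kJ mol^-1 fs
    kB          = .kB,           # kJ mol^-1 K^-1
    eV          = .eV_kJmol,     # kJ/mol per eV
    amu_nm2_fs2 = .amu_nm2_fs2,  # kJ/mol per amu nm^2 fs^-2
    h_SI        = .h_SI,         # J s
    c_SI        = .c_SI,         # m/s
    eps0_SI     = .eps0_SI,      # F/m
    e_SI        = .e_SI,         # C
    NA_SI       = .NA_SI,        # mol^-1
    debye_SI    = .debye_SI      # C m per Debye
  )
}

.hbar <- 63.5078               # kJ mol^-1 fs
.kB <- 8.31446e-3              # kJ mol^-1 K^-1
.eV_kJmol <- 96.48533          # kJ/mol per eV
# 1 amu nm^2 fs^-2 = 1e-3 kg/mol * 1e-18 m^2 / 1e-30 s^2 = 1e9 J/mol
.amu_nm2_fs2 <- 1e6            # kJ/mol per amu nm^2 fs^-2

.h_SI <- 6.62607015e-34
.c_SI <- 2.99792458e8
.eps0_SI <- 8.8541878128e-12
.e_SI <- 1.602176634e-19
.NA_SI <- 6.02214076e23
.debye_SI <- 3.33564e-30
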