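## Physical constants and unit conversions used throughout.
## Internal conventions: coordinates in Angstrom on disk, Bohr internally for
## electronic-structure math; energies internal in Hartree, reported in eV.

#' Physical constants used by equiham
#'
#' A named list of the unit conversions the package relies on:
#' `hartree_eV` (1 Ha in eV), `bohr_A` (1 Bohr in Angstrom), `eV_cm1`
#' (1 eV in cm^-1), `kB_cm1` (Boltzmann constant in cm^-1/K) and
#' `fs_to_cm` (phase-consistent time conversion, see details).
#'
#' @details Time-domain vibronic math is done in hbar = 1 units with energies
#' in cm^-1, so times are measured in cm: `t_cm = 2 * pi * c * t_fs` with
#' c in cm/fs. A phase `omega * t` is then `nu_cm1 * t_cm`.
#'
#' @return Named list of numeric constants.
#' @export
ehConstants <- function() {
  list(
    hartree_eV = 27.211386245988,
    bohr_A     = 0.529177210903,
    eV_cm1     = 8065.544,
    kB_cm1     = 0.6950348,
    fs_to_cm   = 2 * pi * 2.99792458e-5
  )
}

.const <- list(
  hartree_eV = 27.211386245988,
  bohr_A     = 0.529177210903,
  eV_cm1     = 8065.544,
  kB_cm1     = 0.6950348,
  fs_to_cm   = 2 * pi * 2.99792458e-5
)

## Supported elements: symbol -> atomic number
.elementZ <- c(H = 1L, C = 6L)

## sTDA chemical hardness (Hartree), from the global-hardness table used by
## the simplified TDA parameterization (values in eV / Hartree conversion).
.hardnessHa <- c(H = 6.4299 / 27.211386245988,
                 C = 5.0300 / 27.211386245988)
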