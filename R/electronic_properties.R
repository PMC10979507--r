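## Solve the pseudo-eigenproblem and derive one-electron properties:
## MO energies/coefficients, Loewdin charges, transition charges, gaps.

#' Solve for molecular orbitals
#'
#' Symmetric eigensolve of the effective Hamiltonian (the basis is implicit
#' and orthonormal, so no overlap enters). Closed-shell only: the electron
#' count must be even. A deterministic sign convention is applied: the
#' largest-magnitude coefficient of each MO is made positive.
#'
#' @param hamiltonian An [EffectiveHamiltonian-class] or symmetric matrix.
#' @param nElectrons Even electron count, at most `2 * nrow`.
#' @return An [MOSolution-class].
#' @export
solveMOs <- function(hamiltonian, nElectrons) {
  H <- if (is(hamiltonian, "EffectiveHamiltonian"))
    hamiltonianMatrix(hamiltonian) else hamiltonian
  if (!all(is.finite(H))) stop("numerical error: non-finite Hamiltonian entries")
  if (nElectrons %% 2 != 0)
    stop("unsupported: odd electron count (closed-shell only)")
  if (nElectrons > 2 * nrow(H)) stop("more electrons than 2 x orbitals")
  es <- eigen((H + t(H)) / 2, symmetric = TRUE)
  ord <- order(es$values)
  e <- es$values[ord]
  C <- es$vectors[, ord, drop = FALSE]
  for (k in seq_len(ncol(C))) {
    mx <- which.max(abs(C[, k]))
    if (C[mx, k] < 0) C[, k] <- -C[, k]
  }
  new("MOSolution", energies = e, coefficients = C,
      nOcc = as.integer(nElectrons / 2))
}

#' Closed-shell electron count of a neutral geometry
#' @param geometry A [MolecularGeometry-class].
#' @return Integer; errors if the closed-shell count is odd.
#' @export
countElectrons <- function(geometry) {
  ne <- sum(atomicNumbers(geometry)) - netCharge(geometry)
  if (ne %% 2 != 0)
    stop("open-shell electron count ", ne, " not supported")
  as.integer(ne)
}

## fractional occupations per MO (2 each, aufbau), symmetrized over a
## degenerate frontier shell; returns vector of length n_MO
.occupations <- function(solution, degTol = 1e-8) {
  e <- moEnergies(solution)
  nOcc <- nOccupied(solution)
  occ <- numeric(length(e))
  if (nOcc == 0) return(occ)
  occ[seq_len(nOcc)] <- 2
  if (nOcc < length(e) && (e[nOcc + 1] - e[nOcc]) < degTol) {
    shell <- which(abs(e - e[nOcc]) < degTol)
    inShellOcc <- sum(occ[shell])
    occ[shell] <- inShellOcc / length(shell)
    warning("partially occupied degenerate frontier shell: occupation ",
            "symmetrized over ", length(shell), " MOs")
  }
  occ
}

#' Loewdin atomic charges
#'
#' q_A = Z_A - sum_{mu in A} sum_n f_n C_{mu n}^2 with closed-shell
#' occupations f_n = 2 for the lowest N_occ MOs (symmetrized across a
#' partially occupied degenerate frontier shell). The sum rule
#' `sum_A q_A = net charge` is verified, not enforced.
#'
#' @param solution An [MOSolution-class].
#' @param geometry A [MolecularGeometry-class].
#' @param layout A [BasisLayout-class].
#' @return Numeric per-atom charge vector (elementary charges).
#' @export
loewdinCharges <- function(solution, geometry, layout) {
  index <- buildOrbitalIndex(geometry, layout)
  C <- moCoefficients(solution)
  occ <- .occupations(solution)
  pop <- as.numeric((C^2) %*% occ)           # per-orbital population
  q <- atomicNumbers(geometry) -
    as.numeric(tapply(pop, index$atom, sum))
  if (abs(sum(q) - netCharge(geometry)) > 1e-8)
    stop("internal consistency error: Loewdin charges sum to ",
         format(sum(q)), " instead of the net charge")
  q
}

#' Loewdin transition charges between two MOs
#'
#' q_pq^A = sum_{mu in A} C_{mu p} C_{mu q}; symmetric in (p, q). For p = q
#' these are the per-atom populations of MO p (summing to 1); for p != q
#' they sum to zero by MO orthogonality.
#'
#' @param solution An [MOSolution-class].
#' @param geometry A [MolecularGeometry-class].
#' @param layout A [BasisLayout-class].
#' @param p,q MO indices.
#' @return Numeric per-atom vector.
#' @export
transitionCharges <- function(solution, geometry, layout, p, q) {
  C <- moCoefficients(solution)
  if (p < 1 || q < 1 || p > ncol(C) || q > ncol(C))
    stop("index error: MO index out of range")
  index <- buildOrbitalIndex(geometry, layout)
  as.numeric(tapply(C[, p] * C[, q], index$atom, sum))
}

## all transition charges between two MO index sets: array (atom, p, q)
.transitionChargeTensor <- function(solution, geometry, layout, pIdx, qIdx) {
  C <- moCoefficients(solution)
  index <- buildOrbitalIndex(geometry, layout)
  nA <- length(geometry)
  out <- array(0, c(nA, length(pIdx), length(qIdx)))
  split_ <- split(seq_len(nrow(C)), index$atom)
  for (a in seq_len(nA)) {
    Ca <- C[split_[[a]], , drop = FALSE]
    out[a, , ] <- crossprod(Ca[, pIdx, drop = FALSE], Ca[, qIdx, drop = FALSE])
  }
  out
}

#' HOMO-LUMO gap in eV
#'
#' @param solution An [MOSolution-class].
#' @return Positive scalar, eV, for gapped systems.
#' @export
homoLumoGap <- function(solution) {
  e <- moEnergies(solution)
  nOcc <- nOccupied(solution)
  if (nOcc >= length(e))
    stop("undefined-gap error: no virtual MOs")
  (e[nOcc + 1] - e[nOcc]) * .const$hartree_eV
}

#' Export molecular orbitals to a Molden file
#'
#' Writes geometry and MO coefficients in Molden format using STO-3G radial
#' parts for visualization (the model basis is implicit; the export is
#' cosmetic, for orbital inspection only).
#'
#' @param solution An [MOSolution-class].
#' @param geometry A [MolecularGeometry-class].
#' @param layout A [BasisLayout-class] (default minimal layout supported).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeMolden <- function(solution, geometry, layout, path) {
  ## STO-3G exponents/coefficients for H 1s, C 1s/2sp
  sto <- list(
    H = list(list(type = "s", ex = c(3.42525091, 0.62391373, 0.16885540),
                  co = c(0.15432897, 0.53532814, 0.44463454))),
    C = list(list(type = "s", ex = c(71.6168370, 13.0450960, 3.5305122),
                  co = c(0.15432897, 0.53532814, 0.44463454)),
             list(type = "s", ex = c(2.9412494, 0.6834831, 0.2222899),
                  co = c(-0.09996723, 0.39951283, 0.70011547)),
             list(type = "p", ex = c(2.9412494, 0.6834831, 0.2222899),
                  co = c(0.15591627, 0.60768372, 0.39195739))))
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("[Molden Format]")
  w("[Atoms] Angs")
  xyz <- coordinates(geometry)
  for (a in seq_len(length(geometry)))
    w("%-2s %4d %4d %14.8f %14.8f %14.8f", atomSymbols(geometry)[a], a,
      atomicNumbers(geometry)[a], xyz[a, 1], xyz[a, 2], xyz[a, 3])
  w("[GTO]")
  for (a in seq_len(length(geometry))) {
    w("%d 0", a)
    for (shell in sto[[atomSymbols(geometry)[a]]]) {
      w("%s %d 1.00", shell$type, length(shell$ex))
      for (k in seq_along(shell$ex)) w(" %18.10e %18.10e", shell$ex[k], shell$co[k])
    }
    w("")
  }
  w("[MO]")
  C <- moCoefficients(solution)
  ## reorder p components m=(-1,0,1)=(y,z,x) -> Molden (x,y,z)
  index <- buildOrbitalIndex(geometry, layout)
  perm <- seq_len(nrow(index))
  pShells <- unique(index[index$l == 1, c("atom", "shell")])
  if (nrow(pShells)) for (r in seq_len(nrow(pShells))) {
    rows <- .shellSlice(index, pShells$atom[r], pShells$shell[r])
    perm[rows] <- rows[c(3, 1, 2)]
  }
  occ <- .occupations(solution)
  for (k in seq_len(ncol(C))) {
    w(" Sym= A")
    w(" Ene= %16.10f", moEnergies(solution)[k])
    w(" Spin= Alpha")
    w(" Occup= %8.6f", occ[k])
    for (mu in seq_len(nrow(C))) w(" %4d %18.12f", mu, C[perm[mu], k])
  }
  invisible(path)
}
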