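## Simplified Tamm-Dancoff solver: monopole-approximated A matrix from MO
## energies and Loewdin transition charges, CI truncation, AX = Omega X.

#' sTDA parameter set
#'
#' Kernel and truncation parameters of the simplified Tamm-Dancoff scheme:
#' Mataga-Nishimoto-Ohno-Klopman gamma integrals with exchange fraction
#' `ax` and exponents `alpha = alpha1 + alpha2 ax` (exchange channel),
#' `beta = beta1 + beta2 ax` (Coulomb channel); per-element chemical
#' hardness in Hartree.
#'
#' @param ax Fock-exchange fraction of the parent functional (0.2, B3LYP).
#' @param alpha1,alpha2,beta1,beta2 Interpolation exponents.
#' @param hardness Named per-element chemical hardness, Hartree.
#' @param eThresh CI truncation threshold, eV (configurations with diagonal
#'   energy above it become secondary candidates).
#' @param perturbThresh Perturbative selection cutoff, Hartree.
#' @return List of class `STDAParameters`.
#' @export
stdaParameters <- function(ax = 0.2, alpha1 = 1.42, alpha2 = 0.48,
                           beta1 = 0.2, beta2 = 1.83,
                           hardness = .hardnessHa,
                           eThresh = 10, perturbThresh = 1e-4) {
  structure(list(ax = ax, alpha = alpha1 + alpha2 * ax,
                 beta = beta1 + beta2 * ax, hardness = hardness,
                 eThresh = eThresh, perturbThresh = perturbThresh),
            class = "STDAParameters")
}

#' Mataga-Nishimoto-Ohno-Klopman gamma kernels
#'
#' Atom-pair Coulomb (J) and exchange (K) monopole integrals:
#' `gammaK = (R^alpha + etaBar^-alpha)^(-1/alpha)` and
#' `gammaJ = (R^beta + (ax etaBar)^-beta)^(-1/beta)` with R in Bohr and
#' `etaBar` the mean chemical hardness. Both tend to 1/R at large
#' separation and stay finite at R = 0.
#'
#' @param geometry A [MolecularGeometry-class].
#' @param parameters An [stdaParameters()].
#' @return List of class `GammaKernel` with symmetric matrices `gammaJ`,
#'   `gammaK` (Hartree).
#' @export
buildGamma <- function(geometry, parameters = stdaParameters()) {
  syms <- atomSymbols(geometry)
  missing_ <- setdiff(unique(syms), names(parameters$hardness))
  if (length(missing_))
    stop("configuration error: no chemical hardness for ",
         paste(missing_, collapse = ", "))
  eta <- parameters$hardness[syms]
  etaBar <- outer(eta, eta, "+") / 2
  xyz <- coordinates(geometry) / .const$bohr_A
  R <- as.matrix(stats::dist(xyz))
  a <- parameters$alpha; b <- parameters$beta
  gK <- (R^a + etaBar^(-a))^(-1 / a)
  gJ <- (R^b + (parameters$ax * etaBar)^(-b))^(-1 / b)
  dimnames(gJ) <- dimnames(gK) <- NULL
  structure(list(gammaJ = (gJ + t(gJ)) / 2, gammaK = (gK + t(gK)) / 2,
                 parameters = parameters), class = "GammaKernel")
}

## full CI singles configuration table of a solution
.fullCISpace <- function(solution) {
  nOcc <- nOccupied(solution)
  nMO <- length(moEnergies(solution))
  if (nOcc == 0 || nOcc == nMO) stop("no occupied -> virtual excitations")
  expand.grid(i = seq_len(nOcc), a = (nOcc + 1L):nMO)
}

#' Build the monopole-approximated TDA matrix
#'
#' `A_{ia,jb} = delta_ij delta_ab (eps_a - eps_i)
#'  + 2 sum_AB q_ia^A gammaK_AB q_jb^B - sum_AB q_ij^A gammaJ_AB q_ab^B`
#' with Loewdin transition charges from the MO coefficients.
#'
#' @param solution An [MOSolution-class].
#' @param kernel A [buildGamma()] kernel.
#' @param space data.frame of configurations (columns i, a); default full.
#' @param geometry A [MolecularGeometry-class].
#' @param layout A [BasisLayout-class].
#' @return Dense symmetric matrix (Hartree), one row/column per
#'   configuration.
#' @export
buildA <- function(solution, kernel, space = NULL, geometry, layout) {
  if (is.null(space)) space <- .fullCISpace(solution)
  if (nrow(space) == 0) stop("internal error: empty CI space")
  eps <- moEnergies(solution)
  nOcc <- nOccupied(solution)
  occIdx <- sort(unique(space$i))
  virIdx <- sort(unique(space$a))
  Qov <- .transitionChargeTensor(solution, geometry, layout, occIdx, virIdx)
  Qoo <- .transitionChargeTensor(solution, geometry, layout, occIdx, occIdx)
  Qvv <- .transitionChargeTensor(solution, geometry, layout, virIdx, virIdx)
  io <- match(space$i, occIdx); av <- match(space$a, virIdx)
  nC <- nrow(space); nA <- length(geometry)
  ## exchange-type term: 2 q_ia gK q_jb
  Qc <- matrix(0, nA, nC)
  for (k in seq_len(nC)) Qc[, k] <- Qov[, io[k], av[k]]
  A <- 2 * t(Qc) %*% kernel$gammaK %*% Qc
  ## Coulomb-type term: - q_ij gJ q_ab
  GJ <- kernel$gammaJ
  ## precompute gJ-contracted occupied-occupied charges
  for (k in seq_len(nC)) {
    vij <- GJ %*% Qoo[, io[k], ]           # nA x nOccIdx
    for (l in k:nC) {
      val <- sum(vij[, io[l]] * Qvv[, av[k], av[l]])
      A[k, l] <- A[k, l] - val
      if (l > k) A[l, k] <- A[l, k] - val
    }
  }
  diag(A) <- diag(A) + (eps[space$a] - eps[space$i])
  (A + t(A)) / 2
}

#' Truncate the CI space
#'
#' Primary configurations are those whose diagonal TDA energy lies below
#' the energy threshold; remaining configurations whose summed
#' second-order coupling to the primary space exceeds the perturbative
#' cutoff are promoted into the space, the rest are flagged as contributing
#' only a perturbative correction.
#'
#' @param solution An [MOSolution-class].
#' @param kernel A [buildGamma()] kernel.
#' @param geometry,layout Geometry and layout.
#' @param parameters An [stdaParameters()] (energy threshold `eThresh` in
#'   eV, `perturbThresh` in Hartree).
#' @return data.frame of selected configurations (i, a, primary flag),
#'   with the discarded-configuration count in attribute `nDiscarded`.
#' @export
truncateCI <- function(solution, kernel, geometry, layout,
                       parameters = stdaParameters()) {
  if (parameters$eThresh <= 0) stop("parameter error: threshold must be > 0")
  space <- .fullCISpace(solution)
  A <- buildA(solution, kernel, space, geometry, layout)
  dg <- diag(A)
  thr <- parameters$eThresh / .const$hartree_eV
  primary <- dg <= thr
  if (!any(primary))
    stop("empty primary CI space: increase the energy threshold (max ",
         "diagonal ", format(max(dg) * .const$hartree_eV, digits = 4), " eV)")
  secondary <- rep(FALSE, nrow(space))
  cand <- which(!primary)
  if (length(cand)) {
    e2 <- vapply(cand, function(u) {
      den <- pmax(dg[u] - dg[primary], 1e-6)
      sum(A[u, primary]^2 / den)
    }, numeric(1))
    secondary[cand[e2 > parameters$perturbThresh]] <- TRUE
  }
  keep <- primary | secondary
  out <- space[keep, , drop = FALSE]
  out$primary <- primary[keep]
  rownames(out) <- NULL
  attr(out, "nDiscarded") <- sum(!keep)
  out
}

#' Solve the TDA eigenproblem
#'
#' Lowest `nStates` eigenpairs of the symmetric TDA matrix, ascending,
#' with unit-normalized amplitudes; energies converted to eV.
#'
#' @param A Dense symmetric TDA matrix, Hartree.
#' @param nStates Number of states (<= dim(A)).
#' @param space Configuration table matching A's rows.
#' @return An [ExcitationResult-class].
#' @export
solveTDA <- function(A, nStates = min(10L, nrow(A)), space = NULL) {
  if (nStates > nrow(A))
    stop("request error: nStates exceeds the CI dimension")
  es <- eigen((A + t(A)) / 2, symmetric = TRUE)
  ord <- order(es$values)[seq_len(nStates)]
  X <- es$vectors[, ord, drop = FALSE]
  for (k in seq_len(ncol(X))) {
    mx <- which.max(abs(X[, k]))
    if (X[mx, k] < 0) X[, k] <- -X[, k]
  }
  if (is.null(space))
    space <- data.frame(i = NA_integer_, a = NA_integer_,
                        primary = TRUE)[rep(1, nrow(A)), ]
  new("ExcitationResult", energies = es$values[ord] * .const$hartree_eV,
      amplitudes = X, space = space)
}

#' Simplified Tamm-Dancoff excitation energies of a molecule
#'
#' Full pipeline on a predicted (or reference) Hamiltonian: MO solve,
#' gamma kernels, CI truncation, TDA diagonalization.
#'
#' @param hamiltonian [EffectiveHamiltonian-class] or symmetric matrix.
#' @param geometry A [MolecularGeometry-class].
#' @param layout A [BasisLayout-class].
#' @param nStates Number of excited states.
#' @param parameters An [stdaParameters()].
#' @param truncate Apply CI truncation (otherwise the full CIS space).
#' @return An [ExcitationResult-class].
#' @export
stdaExcitations <- function(hamiltonian, geometry, layout,
                            nStates = 5L, parameters = stdaParameters(),
                            truncate = TRUE) {
  sol <- solveMOs(hamiltonian, countElectrons(geometry))
  kern <- buildGamma(geometry, parameters)
  space <- if (truncate)
    truncateCI(sol, kern, geometry, layout, parameters)
  else {
    sp <- .fullCISpace(sol); sp$primary <- TRUE; sp
  }
  A <- buildA(sol, kern, space, geometry, layout)
  solveTDA(A, min(nStates, nrow(A)), space)
}

#' Per-atom transition density of an excited state
#'
#' `w_A = sum_{ia} X_{ia,k} q_ia^A`; the per-atom monopole weights of the
#' transition density, summing to zero by MO orthogonality.
#'
#' @param result An [ExcitationResult-class].
#' @param solution The [MOSolution-class] the result was built from.
#' @param geometry,layout Geometry and layout.
#' @param k Excited-state index.
#' @return Numeric per-atom vector.
#' @export
transitionDensityAtoms <- function(result, solution, geometry, layout, k) {
  X <- cisAmplitudes(result)
  if (k < 1 || k > ncol(X)) stop("index error: state index out of range")
  space <- ciSpace(result)
  out <- numeric(length(geometry))
  for (c_ in seq_len(nrow(space))) {
    q <- transitionCharges(solution, geometry, layout, space$i[c_], space$a[c_])
    out <- out + X[c_, k] * q
  }
  out
}
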