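## Seeded generators for everything the test-suite needs: toy hydrocarbon
## geometries (chains, rings, a programmatic icosahedral C60), teacher models
## with known weights, a distance-decay tight-binding reference that is NOT
## in the linear model class, and stochastic excitation-energy trajectories
## with analytically known autocorrelation.

## all-trans polyene-like chain C_n H_(n+2): sp2 zig-zag in the xy plane
.polyeneChain <- function(nC) {
  stopifnot(nC >= 2)
  ccS <- 1.54; ccD <- 1.34; ch <- 1.09
  ang <- 30 * pi / 180                    # +-30 deg from the x axis
  pos <- matrix(0, nC, 3)
  for (k in 2:nC) {
    b <- if (k %% 2 == 0) ccD else ccS    # alternating double/single
    dir <- c(cos(ang), sin(ang) * (-1)^k, 0)
    pos[k, ] <- pos[k - 1, ] + b * dir
  }
  sym <- rep("C", nC); coords <- pos
  addH <- function(cIdx, dir) {
    sym <<- c(sym, "H")
    coords <<- rbind(coords, pos[cIdx, ] + ch * dir / sqrt(sum(dir^2)))
  }
  for (k in seq_len(nC)) {
    nb <- pos[setdiff(c(k - 1, k + 1), c(0, nC + 1)), , drop = FALSE]
    away <- pos[k, ] * nrow(nb) - colSums(nb)
    if (k == 1 || k == nC) {
      ## terminal CH2: two hydrogens in-plane
      u <- away / sqrt(sum(away^2))
      v <- c(-u[2], u[1], 0)
      addH(k, u * cos(pi / 3) + v * sin(pi / 3))
      addH(k, u * cos(pi / 3) - v * sin(pi / 3))
    } else {
      addH(k, away)
    }
  }
  MolecularGeometry(sym, coords)
}

## benzene-like ring C_n H_n
.ringGeometry <- function(nC = 6L) {
  cc <- 1.40; ch <- 1.09
  R <- cc / (2 * sin(pi / nC))
  th <- 2 * pi * (seq_len(nC) - 1) / nC
  posC <- cbind(R * cos(th), R * sin(th), 0)
  posH <- cbind((R + ch) * cos(th), (R + ch) * sin(th), 0)
  MolecularGeometry(c(rep("C", nC), rep("H", nC)), rbind(posC, posH))
}

#' Programmatic icosahedral C60 (truncated icosahedron)
#'
#' Vertices of the Archimedean truncated icosahedron (all edges equal),
#' scaled to the requested carbon-carbon bond length. Every atom is
#' equivalent under the icosahedral group.
#'
#' @param bond Bond length, Angstrom.
#' @return A [MolecularGeometry-class] with 60 carbon atoms.
#' @export
buildC60 <- function(bond = 1.42) {
  phi <- (1 + sqrt(5)) / 2
  base <- rbind(
    expand.grid(x = 0, y = c(-1, 1), z = c(-3 * phi, 3 * phi)),
    expand.grid(x = c(-1, 1), y = c(-(2 + phi), 2 + phi), z = c(-2 * phi, 2 * phi)),
    expand.grid(x = c(-phi, phi), y = c(-2, 2), z = c(-(2 * phi + 1), 2 * phi + 1)))
  base <- as.matrix(base)
  verts <- rbind(base, base[, c(2, 3, 1)], base[, c(3, 1, 2)])
  verts <- verts * (bond / 2)
  MolecularGeometry(rep("C", nrow(verts)), verts)
}

#' Generate toy hydrocarbon geometries
#'
#' Seeded generator for families of test structures: ideal all-trans
#' polyene chains (`chain`), benzene-like rings (`ring`), thermally
#' jittered chains (`perturbed`), and the icosahedral C60 (`c60`).
#' Random rigid rotations and translations are applied when requested so
#' that no artificial alignment survives.
#'
#' @param family One of "chain", "ring", "perturbed", "c60".
#' @param nStructures Number of geometries.
#' @param seed Integer seed; the output is a pure function of
#'   (family, parameters, seed).
#' @param nCarbons Carbon count for chain/ring families.
#' @param jitter Gaussian coordinate noise, Angstrom (perturbed family).
#' @param rotate Apply random rigid rotations + translations.
#' @return List of [MolecularGeometry-class].
#' @export
makeGeometries <- function(family = c("chain", "ring", "perturbed", "c60"),
                           nStructures = 1L, seed = 1L, nCarbons = 4L,
                           jitter = 0.03, rotate = TRUE) {
  family <- match.arg(family)
  if (family %in% c("chain", "perturbed") && nCarbons %% 2 != 0)
    stop("chain families require an even carbon count (closed-shell polyene)")
  set.seed(seed)
  out <- vector("list", nStructures)
  for (s in seq_len(nStructures)) {
    g <- switch(family,
      chain = .polyeneChain(nCarbons),
      ring = .ringGeometry(nCarbons),
      perturbed = {
        g0 <- .polyeneChain(nCarbons)
        MolecularGeometry(atomSymbols(g0),
          coordinates(g0) + matrix(stats::rnorm(3 * length(g0), sd = jitter),
                                   ncol = 3))
      },
      c60 = buildC60())
    if (rotate) {
      R <- randomRotation()
      shift <- stats::runif(3, -2, 2)
      g <- MolecularGeometry(atomSymbols(g),
        sweep(coordinates(g) %*% t(R), 2, -shift))
    }
    out[[s]] <- g
  }
  out
}

#' Seeded teacher model with known weights
#'
#' Draws random invariant weights for every target block (decaying with
#' lambda) and adds shell-dependent on-site baseline energies through the
#' constant on-site channel, so teacher Hamiltonians have a physically
#' shaped diagonal. Teacher targets are exactly realizable by the model
#' class.
#'
#' @param spec A [radialBasisSpec()].
#' @param layout A [BasisLayout-class].
#' @param elements Element set.
#' @param seed Integer seed.
#' @param scale Weight scale (Hartree-ish magnitude of block entries).
#' @return A [TrainedModel-class] whose weights are the ground truth.
#' @export
teacherModel <- function(spec, layout, elements = names(.elementZ),
                         seed = 1L, scale = 0.08) {
  set.seed(seed)
  ## a zero-weight template needs channel counts; build features of a probe
  probe <- .polyeneChain(2L)
  feats <- moleculeFeatures(probe, spec, elements)
  template <- zeroWeights(feats, layout)
  tb <- targetBlocks(layout, elements)
  weights <- template
  for (r in seq_len(nrow(tb))) {
    nq <- length(template[[tb$wname[r]]])
    weights[[tb$wname[r]]] <-
      stats::rnorm(nq, sd = scale / (1 + tb$lambda[r]) / sqrt(max(nq, 1)))
  }
  ## on-site baselines per (element, shell): constant channel of lambda=0 a-a
  baselines <- list(H = -0.45, C = c(-10.0, -0.75, -0.35))
  for (el in elements) {
    sh <- elementShells(layout, el)
    for (a in seq_len(nrow(sh))) {
      g <- sprintf("on|%s/0/+1|0", el)
      wn <- paste0(g, "#", a, "-", a)
      ch <- feats@channels[[g]]
      ci <- which(ch$type == "const")
      base <- baselines[[el]][min(a, length(baselines[[el]]))]
      ## lambda=0 component of a (2l+1) identity-like diagonal: base*sqrt(2l+1)
      weights[[wn]][ci] <- weights[[wn]][ci] + base * sqrt(2 * sh$l[a] + 1)
    }
  }
  new("TrainedModel", weights = weights, spec = unclass(spec), layout = layout,
      elements = elements, config = list(mode = "teacher", seed = seed),
      lossHistory = numeric())
}

#' Teacher-generated training targets
#'
#' Runs the forward model (features -> blocks -> Hamiltonian -> MOs ->
#' charges) of a teacher and packages the requested target kind.
#'
#' @param geometries List of [MolecularGeometry-class].
#' @param teacher A [TrainedModel-class] from [teacherModel()].
#' @param kind Target kind (see [trainingTarget()]).
#' @param featuresList Optional precomputed features (recomputed otherwise).
#' @return A [trainingTarget()]; the teacher weights stay available for
#'   recovery tests via `attr(, "teacher")`.
#' @export
teacherTargets <- function(geometries, teacher,
                           kind = c("hamiltonian", "eigenvalues",
                                    "eigenvalues_and_charges"),
                           featuresList = NULL) {
  kind <- match.arg(kind)
  spec <- do.call(radialBasisSpec, teacher@spec[c("nMax", "lMax",
    "gaussianWidth", "cutoff", "taperWidth", "lambdaMax")])
  if (is.null(featuresList))
    featuresList <- lapply(geometries, moleculeFeatures, spec = spec,
                           elements = teacher@elements)
  Hs <- list(); eps <- list(); qs <- list()
  for (s in seq_along(geometries)) {
    H <- predictHamiltonian(featuresList[[s]], modelWeights(teacher),
                            geometries[[s]], teacher@layout)
    Hs[[s]] <- hamiltonianMatrix(H)
    sol <- solveMOs(H, countElectrons(geometries[[s]]))
    eps[[s]] <- moEnergies(sol)
    qs[[s]] <- loewdinCharges(sol, geometries[[s]], teacher@layout)
  }
  tt <- switch(kind,
    hamiltonian = trainingTarget(kind, geometries, hamiltonians = Hs),
    eigenvalues = trainingTarget(kind, geometries, eigenvalues = eps),
    eigenvalues_and_charges = trainingTarget(kind, geometries,
                                             eigenvalues = eps, charges = qs))
  attr(tt, "teacher") <- teacher
  attr(tt, "features") <- featuresList
  tt
}

#' Distance-decay tight-binding reference
#'
#' A Slater-Koster-style toy Hamiltonian with exponential distance decay of
#' the hopping integrals - smooth and rotationally covariant like a DFT
#' minimal-basis Fock matrix, but outside the linear feature-model class
#' (no cutoff, exponential radial form). Defaults give gapped spectra for
#' chain hydrocarbon-like topologies at equilibrium bond lengths.
#'
#' @param onsite Named list of per-shell on-site energies, Hartree.
#' @param hoppings Named list of Slater-Koster prefactors at the reference
#'   distance, Hartree: ssSigma, spSigma, ppSigma, ppPi (per species pair
#'   handled by geometric combination rules).
#' @param decay Exponential decay length, Angstrom.
#' @param rRef Reference distance, Angstrom.
#' @param extraVirtuals Add one diffuse high-lying s shell per atom to
#'   emulate a larger basis (for valence-target selection tests).
#' @return List of class `ToyReference`.
#' @export
toyReference <- function(onsite = list(H = -0.40,
                                       C = c(-10.0, -0.75, -0.30)),
                         hoppings = list(ssSigma = -0.45, spSigma = 0.35,
                                         ppSigma = 0.40, ppPi = -0.15),
                         decay = 0.8, rRef = 1.4, extraVirtuals = FALSE) {
  structure(list(onsite = onsite, hoppings = hoppings, decay = decay,
                 rRef = rRef, extraVirtuals = isTRUE(extraVirtuals)),
            class = "ToyReference")
}

## layout used by a toy reference (minimal, plus optional extra s shell)
.toyLayout <- function(reference) {
  sh <- list(H = data.frame(n = 1L, l = 0L),
             C = data.frame(n = c(1L, 2L, 2L), l = c(0L, 0L, 1L)))
  if (reference$extraVirtuals) {
    sh$H <- rbind(sh$H, data.frame(n = 2L, l = 0L))
    sh$C <- rbind(sh$C, data.frame(n = 3L, l = 0L))
  }
  BasisLayout(sh)
}

## Slater-Koster block between the shells of atoms i (rows) and j (cols).
## p order follows real harmonics m = (-1, 0, 1) = (y, z, x).
.toyPairBlock <- function(reference, elI, elJ, rvec) {
  r <- sqrt(sum(rvec^2))
  u <- rvec / r                      # direction cosines (x, y, z)
  dc <- c(u[2], u[3], u[1])          # (y, z, x) ordering
  sc <- exp(-(r - reference$rRef) / reference$decay)
  hp <- reference$hoppings
  shI <- .toyShellKinds(reference, elI)
  shJ <- .toyShellKinds(reference, elJ)
  B <- matrix(0, sum(ifelse(shI == "p", 3, 1)), sum(ifelse(shJ == "p", 3, 1)))
  ri <- 1L
  for (a in seq_along(shI)) {
    ci <- 1L
    da <- if (shI[a] == "p") 3L else 1L
    for (b in seq_along(shJ)) {
      db <- if (shJ[b] == "p") 3L else 1L
      core <- (shI[a] == "core") || (shJ[b] == "core")
      if (!core) {
        vs <- .toyShellScale(shI[a]) * .toyShellScale(shJ[b])
        if (shI[a] != "p" && shJ[b] != "p") {
          B[ri, ci] <- hp$ssSigma * sc * vs
        } else if (shI[a] != "p") {
          B[ri, ci:(ci + 2)] <- hp$spSigma * sc * vs * dc
        } else if (shJ[b] != "p") {
          B[ri:(ri + 2), ci] <- -hp$spSigma * sc * vs * dc
        } else {
          B[ri:(ri + 2), ci:(ci + 2)] <-
            sc * vs * ((hp$ppSigma - hp$ppPi) * outer(dc, dc) +
                       hp$ppPi * diag(3))
        }
      }
      ci <- ci + db
    }
    ri <- ri + da
  }
  B
}

## shell kinds of an element in a toy reference: core/valence-s/p/diffuse
.toyShellKinds <- function(reference, el) {
  kinds <- if (el == "H") "s" else c("core", "s", "p")
  if (reference$extraVirtuals) kinds <- c(kinds, "s*")
  kinds
}

## hopping attenuation per shell kind (diffuse shells couple weakly)
.toyShellScale <- function(kind) if (kind == "s*") 0.25 else 1

#' Build the toy tight-binding Hamiltonian of a geometry
#'
#' @param geometry A [MolecularGeometry-class].
#' @param reference A [toyReference()].
#' @return List with `matrix` (Hartree) and the `layout` it is defined on.
#' @export
toyHamiltonian <- function(geometry, reference = toyReference()) {
  layout <- .toyLayout(reference)
  index <- buildOrbitalIndex(geometry, layout)
  n <- nrow(index)
  H <- matrix(0, n, n)
  syms <- atomSymbols(geometry)
  xyz <- coordinates(geometry)
  for (a in seq_len(length(geometry))) {
    kinds <- .toyShellKinds(reference, syms[a])
    on <- reference$onsite[[syms[a]]]
    pos <- 1L
    rows <- which(index$atom == a)
    for (k in seq_along(kinds)) {
      d <- if (kinds[k] == "p") 3L else 1L
      e <- if (kinds[k] == "s*") 1.5 else on[min(k, length(on))]
      idx <- rows[pos:(pos + d - 1L)]
      H[cbind(idx, idx)] <- e
      pos <- pos + d
    }
  }
  if (length(geometry) > 1) {
    for (i in seq_len(length(geometry) - 1L)) for (j in (i + 1L):length(geometry)) {
      B <- .toyPairBlock(reference, syms[i], syms[j],
                         xyz[j, ] - xyz[i, ])
      ri <- which(index$atom == i); rj <- which(index$atom == j)
      H[ri, rj] <- B
      H[rj, ri] <- t(B)
    }
  }
  list(matrix = H, layout = layout)
}

#' Toy-reference training targets
#'
#' Solves the tight-binding reference for each geometry and returns
#' eigenvalues and Loewdin charges (optionally also the matrices). With
#' `extraVirtuals` references, valence selection
#' ([selectValenceTargets()]) against the minimal layout is applied.
#'
#' @param geometries List of [MolecularGeometry-class].
#' @param reference A [toyReference()].
#' @param includeHamiltonian Also store the reference matrices (only
#'   meaningful for minimal-layout references).
#' @return A [trainingTarget()] of kind "eigenvalues_and_charges".
#' @export
toyReferenceTargets <- function(geometries, reference = toyReference(),
                                includeHamiltonian = FALSE) {
  minimal <- BasisLayout()
  eps <- list(); qs <- list(); Hs <- if (includeHamiltonian) list() else NULL
  for (s in seq_along(geometries)) {
    tb <- toyHamiltonian(geometries[[s]], reference)
    sol <- solveMOs(tb$matrix, countElectrons(geometries[[s]]))
    q <- loewdinCharges(sol, geometries[[s]], tb$layout)
    if (reference$extraVirtuals) {
      sel <- selectValenceTargets(moEnergies(sol), q, geometries[[s]], minimal)
      eps[[s]] <- sel$eigenvalues; qs[[s]] <- sel$charges
    } else {
      eps[[s]] <- moEnergies(sol); qs[[s]] <- q
    }
    if (includeHamiltonian) Hs[[s]] <- tb$matrix
  }
  tt <- trainingTarget("eigenvalues_and_charges", geometries,
                       hamiltonians = Hs, eigenvalues = eps, charges = qs)
  attr(tt, "reference") <- reference
  tt
}

#' Synthetic excitation-energy trajectory
#'
#' Sum of harmonic (undamped, random-phase) or damped-oscillatory
#' Ornstein-Uhlenbeck components with analytically known autocorrelation:
#' an undamped mode contributes `A^2 cos(w t) / 2`, a damped one
#' `A^2 exp(-t / tau) cos(w t)`.
#'
#' @param modes data.frame with columns `freq_cm1`, `coupling_eV` and
#'   optionally `damping_fs` (Inf or NA = undamped harmonic).
#' @param nSteps Number of frames.
#' @param dt Time step, fs.
#' @param temperature Temperature, K (stored for the downstream pipeline).
#' @param seed Integer seed.
#' @param meanEnergy Mean excitation energy, eV.
#' @return An energy trajectory (see [energyTrajectory()]).
#' @export
makeEnergyTrajectory <- function(modes, nSteps = 4096L, dt = 1,
                                 temperature = 300, seed = 1L,
                                 meanEnergy = 3) {
  stopifnot(dt > 0)
  set.seed(seed)
  t <- (seq_len(nSteps) - 1L) * dt
  U <- rep(meanEnergy, nSteps)
  for (k in seq_len(nrow(modes))) {
    omega <- modes$freq_cm1[k] * .const$fs_to_cm  # rad/fs
    A <- modes$coupling_eV[k]
    tau <- if ("damping_fs" %in% names(modes)) modes$damping_fs[k] else Inf
    if (is.na(tau) || !is.finite(tau)) {
      phi <- stats::runif(1, 0, 2 * pi)
      U <- U + A * cos(omega * t + phi)
    } else {
      ## complex AR(1): stationary |z| with Var(Re z) = 1, c(t)=exp(-t/tau)cos(wt)
      rho <- exp((1i * omega - 1 / tau) * dt)
      innovSd <- sqrt((1 - abs(rho)^2))       # per component of CN(0, 2)
      z <- complex(real = stats::rnorm(1), imaginary = stats::rnorm(1))
      x <- numeric(nSteps)
      x[1] <- Re(z)
      for (s in 2:nSteps) {
        z <- z * rho + complex(real = stats::rnorm(1, sd = innovSd),
                               imaginary = stats::rnorm(1, sd = innovSd))
        x[s] <- Re(z)
      }
      U <- U + A * x
    }
  }
  energyTrajectory(t, U, temperature)
}
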