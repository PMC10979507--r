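# equiham

Equivariant regression of effective minimal-basis Hamiltonians for
hydrocarbon-like molecules, with simplified Tamm–Dancoff (sTDA) excited
states and second-order-cumulant vibronic spectra.

## What it does, and for whom

Mean-field quantum chemistry delivers molecular orbitals by an expensive
self-consistent solution of **HC** = **SCε**. `equiham` is for
computational chemists who want a cheap, symmetry-correct surrogate: it
learns an effective single-particle Hamiltonian **H̃** on an *implicit,
orthonormal, minimal* atom-centered basis (H: 1s; C: 1s, 2s, 2p), whose
ordinary eigenproblem directly yields MO energies and coefficients —
no SCF, no overlap. Downstream one-electron machinery then gives Löwdin
charges, HOMO–LUMO gaps, sTDA excitation energies, and vibronic
absorption spectra from excitation-energy trajectories.

The model is a symmetry-adapted linear map. Every atom-pair block of
**H̃** is decomposed into irreducible SO(3) components by real
Clebsch–Gordan coupling, and each component is predicted as

H<sub>ij</sub><sup>pτλμ</sup> = Σ<sub>q</sub> w<sub>q</sub><sup>pτλ</sup> ξ<sub>q</sub><sup>τλμ</sup>(A<sub>ij</sub>),

where ξ are two-center, one-neighbor atom-density correlation features
(pair density ⊗ neighbor density, Clebsch–Gordan coupled, permutation-
and parity-adapted). By construction **H̃**(R·A) = **D**(R) **H̃**(A)
**D**(R)ᵀ under rotations, blocks beyond the feature cutoff are exactly
zero, and relabeling identical atoms permutes rows and columns.

Three training modes are provided:

* **model 1** — direct ridge regression on reference Hamiltonian
  matrices (convex, closed form);
* **model 2** — indirect fit of the *eigenvalues* of **H̃** to reference
  MO energies (gradient-based, through the eigensolve);
* **model 3** — model 2 plus Löwdin-charge targets, which repairs the
  unphysical atomic charges that eigenvalue-only training produces;
  valence-selected targets from larger basis sets are supported.

Seeded synthetic generators (teacher models with known weights, a
distance-decay tight-binding reference, stochastic energy trajectories
with known spectral content) make the whole package testable without any
quantum-chemistry engine or download.

## Worked example

Train model 3 on twenty thermally distorted C2/C4 chains with
tight-binding reference eigenvalues and charges, then predict a fresh
butadiene-like chain:

```r
library(equiham)
layout <- BasisLayout()                      # H: 1s; C: 1s 2s 2p
spec <- radialBasisSpec(nMax = 2, lMax = 1, cutoff = 3.0, lambdaMax = 2)

geoms <- c(makeGeometries("perturbed", 10, seed = 1, nCarbons = 2),
           makeGeometries("perturbed", 10, seed = 2, nCarbons = 4))
targets <- toyReferenceTargets(geoms, includeHamiltonian = TRUE)
feats <- lapply(geoms, moleculeFeatures, spec = spec)

m3 <- fitIndirect(feats, targets, layout,
                  lossConfig("eps-q", maxIterations = 300, seed = 1))

g <- makeGeometries("chain", 1, seed = 7, nCarbons = 4, rotate = FALSE)[[1]]
f <- moleculeFeatures(g, spec)
H <- predictHamiltonian(f, modelWeights(m3), g, layout)
sol <- solveMOs(H, countElectrons(g))
homoLumoGap(sol)                             # 6.739 eV
loewdinCharges(sol, g, layout)               # -0.184 0.013 0.013 -0.184 ...
excitationEnergies(
  stdaExcitations(H, g, layout, nStates = 3))  # 6.747 7.321 11.516 eV
```

The gap (6.74 eV) is the polyene π→π* scale of the tight-binding
reference; the charges put the expected negative partial charge on the
terminal CH2 carbons and sum to zero (closed-shell neutral); the first
sTDA excitation sits just above the gap because the monopole
electron–hole attraction and exchange terms nearly cancel for this toy.

A vibronic spectrum from a synthetic trajectory with one 1400 cm⁻¹ mode:

```r
tr <- makeEnergyTrajectory(data.frame(freq_cm1 = 1400, coupling_eV = 0.05),
                           nSteps = 16384, dt = 1, seed = 3)
J <- spectralDensity(dampCorrelation(energyAutocorrelation(tr),
                                     window = 8000))
J$frequencies[which.max(J$values)]           # 1400 cm-1
```

Shell entry points (`train`, `predict`, `stda`, `spectrum`,
`make-fixtures`) live under `inst/scripts/`, e.g.

```sh
Rscript inst/scripts/spectrum.R --input traj.csv --out-prefix out \
        --damp-ps 10 --temp-K 300 --disorder-fwhm-cm1 400
```

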