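Package: equiham
Title: Equivariant Regression of Effective Minimal-Basis Hamiltonians with
    sTDA Excitations and Cumulant Vibronic Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Symmetry-adapted linear regression of an effective single-particle
    Hamiltonian in an implicit orthonormal minimal atom-centered basis for
    hydrocarbon-like molecules. Two-center one-neighbor atom-density correlation
    features are built by Clebsch-Gordan coupling of real spherical harmonics and
    mapped linearly onto irreducible (SO(3)) blocks of the Hamiltonian. Models can
    be trained directly on Hamiltonian matrices, or indirectly on molecular-orbital
    energies and Loewdin charges (including valence targets from larger basis
    sets), by backpropagation through the symmetric eigensolve. Predicted orbitals
    feed a simplified Tamm-Dancoff (sTDA) excited-state solver with
    monopole-approximated integrals, and a second-order-cumulant pipeline turns
    excitation-energy trajectories into spectral densities and vibronic absorption
    spectra with static disorder. Seeded synthetic generators (teacher models, a
    distance-decay tight-binding reference, stochastic energy trajectories) supply
    every input needed for testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'equiham-package.R'
    'constants.R'
    'angular.R'
    'allClasses.R'
    'molecular_system.R'
    'equivariant_features.R'
    'hamiltonian_model.R'
    'electronic_properties.R'
    'indirect_training.R'
    'stda_excitations.R'
    'vibronic_spectra.R'
    'synthetic_data.R'
    'container.R'
    'cli_workflows.R'
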