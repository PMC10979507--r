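## Shared fixtures, built once per test run. Everything is generated in
## code from fixed seeds; specs are kept small so the suite stays fast.

fx <- new.env()

fxSpec <- function() radialBasisSpec(nMax = 2, lMax = 1, cutoff = 3.0,
                                     lambdaMax = 2)
fxLayout <- function() BasisLayout()

## a mixed set of perturbed chains (C2 and C4) with cached features
fxGeometries <- function() {
  if (is.null(fx$geoms))
    fx$geoms <- c(makeGeometries("perturbed", 6, seed = 3, nCarbons = 2),
                  makeGeometries("perturbed", 6, seed = 4, nCarbons = 4))
  fx$geoms
}

fxFeatures <- function() {
  if (is.null(fx$feats))
    fx$feats <- lapply(fxGeometries(), moleculeFeatures, spec = fxSpec())
  fx$feats
}

fxTeacher <- function() {
  if (is.null(fx$teacher))
    fx$teacher <- teacherModel(fxSpec(), fxLayout(), seed = 11)
  fx$teacher
}

fxTeacherHTargets <- function() {
  if (is.null(fx$ttH))
    fx$ttH <- teacherTargets(fxGeometries(), fxTeacher(), "hamiltonian",
                             featuresList = fxFeatures())
  fx$ttH
}

## ethylene at rest, no rotation: a convenient deterministic molecule
fxEthylene <- function() makeGeometries("chain", 1, seed = 1, nCarbons = 2,
                                        rotate = FALSE)[[1]]

## random weights compatible with the fixture features
fxRandomWeights <- function(seed = 2, sd = 0.1) {
  set.seed(seed)
  lapply(zeroWeights(fxFeatures()[[1]], fxLayout()),
         function(v) rnorm(length(v), sd = sd))
}

## pack a named weight list into one vector (test-local convenience)
fxPack <- function(w) unlist(w, use.names = FALSE)

## block-diagonal orbital rotation matrix for equivariance oracles,
## built from independent spherical-harmonic evaluation
fxOrbitalRotation <- function(geometry, layout, R) {
  index <- buildOrbitalIndex(geometry, layout)
  n <- nrow(index)
  D <- matrix(0, n, n)
  pos <- 1L
  while (pos <= n) {
    l <- index$l[pos]
    d <- 2L * l + 1L
    D[pos:(pos + d - 1L), pos:(pos + d - 1L)] <- wignerDReal(l, R)
    pos <- pos + d
  }
  D
}

fxRotate <- function(geometry, R, shift = c(0, 0, 0)) {
  MolecularGeometry(atomSymbols(geometry),
                    sweep(coordinates(geometry) %*% t(R), 2, -shift))
}
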