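test_that("gamma kernels have the Coulomb asymptote and stay finite", {
  bohr <- 0.529177210903
  ## the Coulomb channel's small exponent beta makes its 1/R approach very
  ## slow, so the asymptote is checked far out for gammaJ
  g <- MolecularGeometry(c("C", "H"), rbind(c(0, 0, 0), c(0, 0, 500 * bohr)))
  k <- buildGamma(g)
  expect_lt(abs(k$gammaK[1, 2] - 1 / 500) / (1 / 500), 0.01)
  gFar <- MolecularGeometry(c("C", "H"), rbind(c(0, 0, 0), c(0, 0, 1e6 * bohr)))
  kF <- buildGamma(gFar)
  expect_lt(abs(kF$gammaJ[1, 2] - 1e-6) / 1e-6, 0.01)
  expect_lt(abs(kF$gammaK[1, 2] - 1e-6) / 1e-6, 0.01)
  ## R = 0 limit: finite, controlled by the hardness
  p <- stdaParameters()
  eta <- mean(p$hardness[c("C", "C")])
  g0 <- MolecularGeometry(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 1e-9)))
  k0 <- buildGamma(g0)
  expect_lt(abs(k0$gammaK[1, 2] - eta), 1e-6)
  expect_lt(abs(k0$gammaJ[1, 2] - p$ax * eta), 1e-6)
  ## symmetric for random geometries
  set.seed(71)
  gr <- MolecularGeometry(rep(c("C", "H"), 3), matrix(rnorm(18, sd = 2), 6))
  kr <- buildGamma(gr)
  expect_lt(max(abs(kr$gammaJ - t(kr$gammaJ))), 1e-14)
  expect_lt(max(abs(kr$gammaK - t(kr$gammaK))), 1e-14)
  expect_error(buildGamma(gr, stdaParameters(hardness = c(H = 0.2))),
               "hardness")
})

test_that("the TDA matrix reduces to orbital gaps when the kernels vanish", {
  g <- fxEthylene()
  tb <- toyHamiltonian(g)
  sol <- solveMOs(tb$matrix, countElectrons(g))
  kern <- buildGamma(g)
  zero <- kern
  zero$gammaJ <- zero$gammaJ * 0
  zero$gammaK <- zero$gammaK * 0
  sp <- equiham:::.fullCISpace(sol)
  A <- buildA(sol, zero, sp, g, tb$layout)
  gaps <- moEnergies(sol)[sp$a] - moEnergies(sol)[sp$i]
  expect_lt(max(abs(A - diag(gaps))), 1e-12)
  ## with kernels on, A stays symmetric
  Afull <- buildA(sol, kern, sp, g, tb$layout)
  expect_lt(max(abs(Afull - t(Afull))), 1e-12)
})

test_that("a hand-built 2-configuration system matches pencil and paper", {
  ## fake 3-orbital, 2-atom solution: 1 occupied, 2 virtuals
  g <- MolecularGeometry(c("C", "H"), rbind(c(0, 0, 0), c(0, 0, 1.1)))
  layout <- BasisLayout(list(C = data.frame(n = 1:2, l = c(0L, 0L)),
                             H = data.frame(n = 1L, l = 0L)))
  set.seed(72)
  M <- qr.Q(qr(matrix(rnorm(9), 3)))
  eps <- c(-0.5, 0.1, 0.4)
  sol <- new("MOSolution", energies = eps, coefficients = M, nOcc = 1L)
  kern <- buildGamma(g)
  sp <- data.frame(i = c(1L, 1L), a = c(2L, 3L))
  A <- buildA(sol, kern, sp, g, layout)
  ## manual evaluation of the monopole formula
  qAt <- function(p, q) transitionCharges(sol, g, layout, p, q)
  man <- matrix(0, 2, 2)
  for (k in 1:2) for (l in 1:2) {
    ia <- sp[k, ]; jb <- sp[l, ]
    man[k, l] <- 2 * sum(outer(qAt(ia$i, ia$a), qAt(jb$i, jb$a)) * kern$gammaK) -
      sum(outer(qAt(ia$i, jb$i), qAt(ia$a, jb$a)) * kern$gammaJ)
  }
  man <- man + diag(eps[sp$a] - eps[sp$i])
  expect_lt(max(abs(A - man)), 1e-12)
})

test_that("CI truncation keeps low configurations and promotes coupled ones", {
  g <- fxEthylene()
  tb <- toyHamiltonian(g)
  sol <- solveMOs(tb$matrix, countElectrons(g))
  kern <- buildGamma(g)
  full <- equiham:::.fullCISpace(sol)
  ## threshold above everything retains the full CIS space
  spAll <- truncateCI(sol, kern, g, tb$layout,
                      stdaParameters(eThresh = 1e5))
  expect_equal(nrow(spAll), nrow(full))
  ## threshold below everything errors
  expect_error(truncateCI(sol, kern, g, tb$layout,
                          stdaParameters(eThresh = 1e-3)), "threshold")
  ## defaults: truncated-then-solved lowest state close to the full solve
  spDef <- truncateCI(sol, kern, g, tb$layout, stdaParameters(eThresh = 12))
  Afull <- buildA(sol, kern, full, g, tb$layout)
  Atr <- buildA(sol, kern, spDef, g, tb$layout)
  w1 <- solveTDA(Afull, 1)
  w2 <- solveTDA(Atr, 1)
  expect_lt(abs(excitationEnergies(w1)[1] - excitationEnergies(w2)[1]), 0.01)
})

test_that("the TDA solver matches closed forms and a second eigensolver", {
  ## diagonal A: energies are the sorted diagonal
  d <- c(0.4, 0.1, 0.7)
  r <- solveTDA(diag(d), 3)
  expect_equal(excitationEnergies(r), sort(d) * 27.211386245988,
               tolerance = 1e-10)
  ## 2x2 closed form
  a <- 0.3; b <- 0.5; cc <- 0.07
  ev <- (a + b) / 2 + c(-1, 1) * sqrt(((a - b) / 2)^2 + cc^2)
  r2 <- solveTDA(rbind(c(a, cc), c(cc, b)), 2)
  expect_equal(excitationEnergies(r2), sort(ev) * 27.211386245988,
               tolerance = 1e-10)
  ## random 50x50 against the dense eigensolver
  set.seed(73)
  A <- matrix(rnorm(2500), 50); A <- (A + t(A)) / 2
  r3 <- solveTDA(A, 50)
  expect_lt(max(abs(excitationEnergies(r3) / 27.211386245988 -
                    sort(eigen(A, symmetric = TRUE)$values))), 1e-10)
  expect_error(solveTDA(diag(3), 4), "nStates")
})

test_that("per-atom transition densities obey the sum rule and phase freedom", {
  g <- fxEthylene()
  tb <- toyHamiltonian(g)
  sol <- solveMOs(tb$matrix, countElectrons(g))
  res <- stdaExcitations(tb$matrix, g, tb$layout, nStates = 3,
                         truncate = FALSE)
  for (k in 1:3) {
    td <- transitionDensityAtoms(res, sol, g, tb$layout, k)
    expect_lt(abs(sum(td)), 1e-10)
  }
  ## single-configuration state equals that configuration's charges
  spOne <- data.frame(i = nOccupied(sol), a = nOccupied(sol) + 1L,
                      primary = TRUE)
  resOne <- new("ExcitationResult", energies = 1, amplitudes = matrix(1),
                space = spOne)
  td1 <- transitionDensityAtoms(resOne, sol, g, tb$layout, 1)
  expect_equal(td1, transitionCharges(sol, g, tb$layout, spOne$i, spOne$a))
  ## sign flip of the amplitude column leaves magnitudes unchanged
  resFlip <- new("ExcitationResult", energies = 1, amplitudes = matrix(-1),
                 space = spOne)
  expect_equal(abs(transitionDensityAtoms(resFlip, sol, g, tb$layout, 1)),
               abs(td1))
  expect_error(transitionDensityAtoms(res, sol, g, tb$layout, 99), "index")
})

test_that("sTDA energies are invariant under rigid motion of the molecule", {
  layout <- fxLayout()
  spec <- fxSpec()
  w <- fxRandomWeights(seed = 74)
  g <- fxGeometries()[[7]]
  om <- function(gg) {
    H <- predictHamiltonian(moleculeFeatures(gg, spec), w, gg, layout)
    excitationEnergies(stdaExcitations(H, gg, layout, nStates = 3,
                                       truncate = FALSE))
  }
  set.seed(75)
  R <- randomRotation()
  expect_lt(max(abs(om(g) - om(fxRotate(g, R, c(1, -2, 0.5))))), 1e-6)
})

test_that("positive HOMO-LUMO gaps give positive excitation energies", {
  for (g in list(fxEthylene(),
                 makeGeometries("ring", 1, seed = 1, nCarbons = 6,
                                rotate = FALSE)[[1]])) {
    tb <- toyHamiltonian(g)
    sol <- solveMOs(tb$matrix, countElectrons(g))
    expect_gt(homoLumoGap(sol), 0)
    res <- stdaExcitations(tb$matrix, g, tb$layout, nStates = 5,
                           truncate = FALSE)
    expect_true(all(excitationEnergies(res) > 0))
  }
})
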