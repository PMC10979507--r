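test_that("irrep decomposition is exact, Parseval, and invertible", {
  set.seed(41)
  ## 1s-1s block: single scalar
  b <- matrix(0.37, 1, 1)
  ir <- decomposeToIrreps(b, 0, 0)
  expect_equal(ir[["0"]], 0.37)
  ## p-p block: 1 + 3 + 5 components, norm preserved
  for (rep_ in 1:20) {
    B <- matrix(rnorm(9), 3, 3)
    ir <- decomposeToIrreps(B, 1, 1)
    expect_equal(vapply(ir, length, integer(1)),
                 c("0" = 1L, "1" = 3L, "2" = 5L))
    expect_lt(abs(sum(unlist(ir)^2) - sum(B^2)), 1e-12)
    expect_lt(max(abs(recomposeFromIrreps(ir, 1, 1) - B)), 1e-12)
  }
  ## mixed s-p and rectangular round trips
  for (dims in list(c(0, 1), c(1, 2), c(0, 2))) {
    B <- matrix(rnorm((2 * dims[1] + 1) * (2 * dims[2] + 1)),
                2 * dims[1] + 1)
    ir <- decomposeToIrreps(B, dims[1], dims[2])
    expect_lt(max(abs(recomposeFromIrreps(ir, dims[1], dims[2]) - B)), 1e-12)
  }
  expect_error(decomposeToIrreps(matrix(0, 2, 3), 1, 1), "shape")
  expect_error(recomposeFromIrreps(list("0" = 0), 1, 1), "incomplete")
  ## all-zero irreps -> zero sub-matrix; scalar-only content -> diagonal
  z <- recomposeFromIrreps(list("0" = 0, "1" = numeric(3), "2" = numeric(5)),
                           1, 1)
  expect_true(all(z == 0))
  d <- recomposeFromIrreps(list("0" = 1, "1" = numeric(3), "2" = numeric(5)),
                           1, 1)
  expect_lt(max(abs(d - diag(3) * d[1, 1])), 1e-14)
})

test_that("block prediction is linear and homogeneous in the weights", {
  f <- fxFeatures()[[1]]
  layout <- fxLayout()
  w0 <- zeroWeights(f, layout)
  ir0 <- predictBlocks(f, w0, layout)
  for (g in names(ir0)) for (b in names(ir0[[g]]))
    expect_true(all(ir0[[g]][[b]] == 0))
  w <- fxRandomWeights(seed = 42)
  ir1 <- predictBlocks(f, w, layout)
  ir2 <- predictBlocks(f, lapply(w, function(v) 2 * v), layout)
  for (g in names(ir1)) for (b in names(ir1[[g]]))
    expect_lt(max(abs(ir2[[g]][[b]] - 2 * ir1[[g]][[b]])), 1e-12)
})

test_that("assembled Hamiltonians are symmetric with zero blocks beyond cutoff", {
  layout <- fxLayout()
  spec <- fxSpec()
  w <- fxRandomWeights(seed = 43)
  ## two carbons beyond the cutoff: block-diagonal matrix
  g <- MolecularGeometry(c("C", "C"), rbind(c(0, 0, 0), c(6, 0, 0)))
  f <- moleculeFeatures(g, spec)
  H <- hamiltonianMatrix(predictHamiltonian(f, w, g, layout))
  expect_lt(max(abs(H - t(H))), 1e-12)
  expect_identical(max(abs(H[1:5, 6:10])), 0)
  ## single atom: matrix equals its on-site block
  g1 <- MolecularGeometry("C", matrix(0, 1, 3))
  f1 <- moleculeFeatures(g1, spec)
  H1 <- hamiltonianMatrix(predictHamiltonian(f1, w, g1, layout))
  expect_equal(dim(H1), c(5L, 5L))
})

test_that("the Hamiltonian map is equivariant end to end", {
  layout <- fxLayout()
  spec <- fxSpec()
  w <- fxRandomWeights(seed = 44)
  set.seed(45)
  for (g in fxGeometries()[c(2, 8)]) {
    H <- hamiltonianMatrix(predictHamiltonian(moleculeFeatures(g, spec), w,
                                              g, layout))
    for (rep_ in 1:3) {
      R <- randomRotation()
      g2 <- fxRotate(g, R, runif(3, -1, 1))
      H2 <- hamiltonianMatrix(predictHamiltonian(moleculeFeatures(g2, spec),
                                                 w, g2, layout))
      D <- fxOrbitalRotation(g, layout, R)
      expect_lt(max(abs(H2 - D %*% H %*% t(D))), 1e-8)
      ## spectrum under rotation
      expect_lt(max(abs(eigen(H2, symmetric = TRUE, only.values = TRUE)$values -
                        eigen(H, symmetric = TRUE, only.values = TRUE)$values)),
                1e-8)
    }
  }
})

test_that("relabeling identical atoms permutes Hamiltonian rows/columns", {
  layout <- fxLayout()
  spec <- fxSpec()
  w <- fxRandomWeights(seed = 46)
  g <- fxEthylene()
  perm <- c(2, 1, 5, 6, 3, 4)
  g2 <- MolecularGeometry(atomSymbols(g)[perm], coordinates(g)[perm, ])
  H <- hamiltonianMatrix(predictHamiltonian(moleculeFeatures(g, spec), w, g,
                                            layout))
  H2 <- hamiltonianMatrix(predictHamiltonian(moleculeFeatures(g2, spec), w,
                                             g2, layout))
  idx <- buildOrbitalIndex(g, layout)
  idx2 <- buildOrbitalIndex(g2, layout)
  pmap <- integer(nrow(idx))
  for (aNew in seq_along(perm))
    pmap[which(idx2$atom == aNew)] <- which(idx$atom == perm[aNew])
  expect_lt(max(abs(H2 - H[pmap, pmap])), 1e-12)
})

test_that("structure decomposition inverts assembly", {
  layout <- fxLayout()
  f <- fxFeatures()[[3]]
  g <- fxGeometries()[[3]]
  w <- fxRandomWeights(seed = 47)
  H <- predictHamiltonian(f, w, g, layout)
  ir <- decomposeStructure(H, g, layout, f)
  H2 <- assembleHamiltonian(ir, g, layout, f)
  expect_lt(max(abs(hamiltonianMatrix(H2) - hamiltonianMatrix(H))), 1e-12)
})

test_that("the precompiled assembly operator matches and is adjoint-exact", {
  layout <- fxLayout()
  f <- fxFeatures()[[4]]
  g <- fxGeometries()[[4]]
  w <- fxRandomWeights(seed = 48)
  op <- equiham:::.assemblyOperator(f, layout, g)
  H1 <- hamiltonianMatrix(predictHamiltonian(f, w, g, layout))
  H2 <- equiham:::.operatorHamiltonian(op, w)
  expect_lt(max(abs(H1 - H2)), 1e-13)
  set.seed(48)
  G <- matrix(rnorm(length(H1)), nrow(H1)); G <- G + t(G)
  gw <- equiham:::.operatorGradient(op, G)
  lhs <- sum(H2 * G)
  rhs <- sum(mapply(function(a, b) sum(a * b), gw[names(w)], w))
  expect_lt(abs(lhs - rhs), 1e-10)
})

test_that("Loewdin orthogonalization reproduces generalized eigenvalues", {
  ## identity overlap: unchanged
  set.seed(49)
  H <- matrix(rnorm(16), 4); H <- H + t(H)
  expect_lt(max(abs(lowdinOrthogonalize(H, diag(4)) - H)), 1e-12)
  ## 2x2 oracle via the generalized eigensolver (whitening construction)
  H2 <- rbind(c(0, 1), c(1, 0)); S2 <- rbind(c(1, 0.5), c(0.5, 1))
  M <- lowdinOrthogonalize(H2, S2)
  es <- eigen(S2, symmetric = TRUE)
  W <- diag(1 / sqrt(es$values)) %*% t(es$vectors)
  genEv <- sort(eigen(W %*% H2 %*% t(W), symmetric = TRUE)$values)
  expect_lt(max(abs(sort(eigen(M, symmetric = TRUE)$values) - genEv)), 1e-10)
  ## random SPD overlap: result symmetric, eigenvalues match the pencil
  A <- matrix(rnorm(25), 5)
  S <- crossprod(A) + diag(5)
  M <- lowdinOrthogonalize(H <- {B <- matrix(rnorm(25), 5); B + t(B)}, S)
  expect_lt(max(abs(M - t(M))), 1e-12)
  expect_error(lowdinOrthogonalize(diag(2), -diag(2)), "positive-definite")
})

test_that("off-site block count grows linearly on chains at fixed cutoff", {
  spec <- fxSpec()
  counts <- vapply(c(4L, 8L, 12L), function(n) {
    g <- makeGeometries("chain", 1, seed = 1, nCarbons = n, rotate = FALSE)[[1]]
    sum(!neighborPairs(g, spec$cutoff)$onsite)
  }, numeric(1))
  ## linear growth: constant per-carbon increment
  inc <- diff(counts)
  expect_equal(inc[1], inc[2])
})
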