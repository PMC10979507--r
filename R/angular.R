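## Angular-momentum algebra: real/complex spherical harmonics, Clebsch-Gordan
## coefficients (complex Condon-Shortley basis and transformed to the real
## basis), and real Wigner rotation matrices. Everything is cached per l (or
## per (l1,l2,lambda)) in a package-local environment.

.angCache <- new.env(parent = emptyenv())

## Associated Legendre P_l^m(x), m >= 0, WITHOUT Condon-Shortley phase.
## Returns matrix n_x rows, columns m = 0..l for the given l.
.assocLegendre <- function(l, x) {
  x <- as.numeric(x)
  nx <- length(x)
  s <- sqrt(pmax(0, 1 - x^2))
  ## P[m][l] built by standard recurrences; store only target l
  out <- matrix(0, nx, l + 1L)
  for (m in 0:l) {
    ## P_m^m = (2m-1)!! s^m
    pmm <- rep(1, nx)
    if (m > 0) {
      df <- prod(seq(1, 2 * m - 1, by = 2))
      pmm <- df * s^m
    }
    if (l == m) {
      out[, m + 1L] <- pmm
      next
    }
    pm1 <- x * (2 * m + 1) * pmm       # P_{m+1}^m
    if (l == m + 1L) {
      out[, m + 1L] <- pm1
      next
    }
    pprev <- pmm; pcur <- pm1
    for (ll in (m + 2L):l) {
      pnew <- ((2 * ll - 1) * x * pcur - (ll + m - 1) * pprev) / (ll - m)
      pprev <- pcur; pcur <- pnew
    }
    out[, m + 1L] <- pcur
  }
  out
}

#' Real spherical harmonics
#'
#' Evaluates the orthonormal real spherical harmonics of order `l` at unit
#' vectors, ordered by component mu = -l..+l (sin-type components for mu < 0,
#' cos-type for mu > 0).
#'
#' @param l Angular momentum (integer >= 0).
#' @param xyz Numeric matrix (n x 3) of direction vectors (normalized
#'   internally; the zero vector is rejected).
#' @return Numeric matrix n x (2l+1).
#' @export
realSphericalHarmonics <- function(l, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  r <- sqrt(rowSums(xyz^2))
  if (any(r < 1e-300)) stop("realSphericalHarmonics: zero direction vector")
  u <- xyz / r
  ct <- pmin(1, pmax(-1, u[, 3]))
  phi <- atan2(u[, 2], u[, 1])
  P <- .assocLegendre(l, ct)
  n <- nrow(u)
  Y <- matrix(0, n, 2 * l + 1L)
  for (m in 0:l) {
    K <- sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
    if (m == 0) {
      Y[, l + 1L] <- K * P[, 1L]
    } else {
      Y[, l + 1L + m] <- sqrt(2) * K * P[, m + 1L] * cos(m * phi)
      Y[, l + 1L - m] <- sqrt(2) * K * P[, m + 1L] * sin(m * phi)
    }
  }
  Y
}

## Complex spherical harmonics with Condon-Shortley phase, columns m = -l..l.
.complexSphericalHarmonics <- function(l, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  r <- sqrt(rowSums(xyz^2))
  u <- xyz / r
  ct <- pmin(1, pmax(-1, u[, 3]))
  phi <- atan2(u[, 2], u[, 1])
  P <- .assocLegendre(l, ct)
  n <- nrow(u)
  Y <- matrix(0 + 0i, n, 2 * l + 1L)
  for (m in 0:l) {
    K <- sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
    Yp <- (-1)^m * K * P[, m + 1L] * exp(1i * m * phi)
    Y[, l + 1L + m] <- Yp
    if (m > 0) Y[, l + 1L - m] <- (-1)^m * Conj(Yp)
  }
  Y
}

## Deterministic, well-spread unit vectors (Fibonacci sphere).
.fibSphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  th <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(th), r * sin(th), z)
}

## Unitary A(l): Y^c_{lm} = sum_mu A[m,mu] Y^r_{l mu}, solved numerically once.
.complexToRealMatrix <- function(l) {
  key <- paste0("A", l)
  if (!is.null(.angCache[[key]])) return(.angCache[[key]])
  pts <- .fibSphere(max(4L * (2L * l + 1L), 24L))
  Mr <- realSphericalHarmonics(l, pts)
  Mc <- .complexSphericalHarmonics(l, pts)
  At <- qr.solve(Mr, Re(Mc)) + 1i * qr.solve(Mr, Im(Mc))  # Mc = Mr %*% At
  A <- t(At)
  .angCache[[key]] <- A
  A
}

#' Clebsch-Gordan coefficient (complex basis)
#'
#' Condon-Shortley Clebsch-Gordan coefficient <j1 m1 j2 m2 | J M> from the
#' Racah closed form.
#'
#' @param j1,m1,j2,m2,J,M Integer angular momentum quantum numbers.
#' @return Numeric scalar.
#' @export
clebschGordan <- function(j1, m1, j2, m2, J, M) {
  if (m1 + m2 != M) return(0)
  if (J < abs(j1 - j2) || J > j1 + j2) return(0)
  if (abs(m1) > j1 || abs(m2) > j2 || abs(M) > J) return(0)
  lf <- function(n) lgamma(n + 1)
  pre <- 0.5 * (log(2 * J + 1) +
    lf(J + j1 - j2) + lf(J - j1 + j2) + lf(j1 + j2 - J) - lf(j1 + j2 + J + 1) +
    lf(J + M) + lf(J - M) + lf(j1 - m1) + lf(j1 + m1) + lf(j2 - m2) + lf(j2 + m2))
  kmin <- max(0, j2 - J - m1, j1 + m2 - J)
  kmax <- min(j1 + j2 - J, j1 - m1, j2 + m2)
  if (kmax < kmin) return(0)
  s <- 0
  for (k in kmin:kmax) {
    lt <- lf(k) + lf(j1 + j2 - J - k) + lf(j1 - m1 - k) + lf(j2 + m2 - k) +
      lf(J - j2 + m1 + k) + lf(J - j1 - m2 + k)
    s <- s + (-1)^k * exp(pre - lt)
  }
  s
}

## Complex CG tensor C[M, m1, m2] for (l1, l2) -> L; dims (2L+1, 2l1+1, 2l2+1)
.cgComplexTensor <- function(l1, l2, L) {
  C <- array(0, c(2 * L + 1L, 2 * l1 + 1L, 2 * l2 + 1L))
  for (m1 in -l1:l1) for (m2 in -l2:l2) {
    M <- m1 + m2
    if (abs(M) <= L)
      C[M + L + 1L, m1 + l1 + 1L, m2 + l2 + 1L] <- clebschGordan(l1, m1, l2, m2, L, M)
  }
  C
}

#' Real-basis Clebsch-Gordan coupling tensor
#'
#' Coupling tensor W such that for real-harmonic coefficient vectors x (order
#' l1) and y (order l2), `z[mu] = sum_{m1,m2} W[mu,m1,m2] x[m1] y[m2]` is an
#' order-`L` real spherical tensor (rotates with the real Wigner matrix of
#' order L). Rows of W are orthonormal in the (m1, m2) index pair.
#'
#' @param l1,l2 Orders of the two factors.
#' @param L Output order, `abs(l1-l2) <= L <= l1+l2`.
#' @return Array of dim `(2L+1, 2l1+1, 2l2+1)`.
#' @export
cgReal <- function(l1, l2, L) {
  key <- sprintf("W_%d_%d_%d", l1, l2, L)
  if (!is.null(.angCache[[key]])) return(.angCache[[key]])
  if (L < abs(l1 - l2) || L > l1 + l2)
    stop("cgReal: L outside |l1-l2|..l1+l2")
  Cc <- .cgComplexTensor(l1, l2, L)
  A1 <- .complexToRealMatrix(l1)
  A2 <- .complexToRealMatrix(l2)
  AL <- .complexToRealMatrix(L)
  d1 <- 2 * l1 + 1L; d2 <- 2 * l2 + 1L; dL <- 2 * L + 1L
  ## W[mu, mu1, mu2] = sum conj(AL[M,mu]) C[M,m1,m2] A1[m1,mu1] A2[m2,mu2]
  Cm <- matrix(Cc, dL, d1 * d2)               # M x (m1 m2)
  T1 <- Conj(t(AL)) %*% Cm                    # mu x (m1 m2)
  W <- array(T1, c(dL, d1, d2))
  ## contract factor transforms
  Wm <- matrix(aperm(W, c(2, 1, 3)), d1, dL * d2)
  Wm <- t(A1) %*% Wm
  W <- aperm(array(Wm, c(d1, dL, d2)), c(2, 1, 3))
  Wm <- matrix(aperm(W, c(3, 1, 2)), d2, dL * d1)
  Wm <- t(A2) %*% Wm
  W <- aperm(array(Wm, c(d2, dL, d1)), c(2, 3, 1))
  ## a global phase makes W real: multiply by i when l1+l2+L is odd
  if ((l1 + l2 + L) %% 2 == 1) W <- W * 1i
  if (max(abs(Im(W))) > 1e-10)
    stop("cgReal: residual imaginary part ", max(abs(Im(W))))
  W <- Re(W)
  ## unitarity check on the full coupled map
  Wm <- matrix(W, dL, d1 * d2)
  if (max(abs(Wm %*% t(Wm) - diag(dL))) > 1e-12 * max(1, dL))
    stop("cgReal: rows not orthonormal")
  .angCache[[key]] <- W
  W
}

#' Real Wigner rotation matrix
#'
#' Orthogonal matrix D of order `l` with
#' `Y^r_l(R x) = D %*% Y^r_l(x)` for the real spherical harmonics, built
#' numerically from harmonic sampling on a deterministic point set.
#'
#' @param l Order.
#' @param R 3x3 proper rotation matrix.
#' @return Orthogonal `(2l+1) x (2l+1)` matrix.
#' @export
wignerDReal <- function(l, R) {
  if (l == 0) return(matrix(1, 1, 1))
  pts <- .fibSphere(max(4L * (2L * l + 1L), 24L))
  B <- realSphericalHarmonics(l, pts)
  Bp <- realSphericalHarmonics(l, pts %*% t(R))
  D <- t(qr.solve(B, Bp))
  D
}

#' Random proper rotation matrix
#'
#' Uniform (Haar) random rotation from a QR decomposition of a Gaussian
#' matrix, with determinant fixed to +1.
#'
#' @param rng Optional function returning n standard normals (defaults to
#'   [stats::rnorm]); pass a seeded generator for reproducibility.
#' @return 3x3 rotation matrix.
#' @export
randomRotation <- function(rng = stats::rnorm) {
  M <- matrix(rng(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  Q <- Q %*% diag(d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

## Block-diagonal real Wigner matrix over the orbitals of a structure,
## used for end-to-end equivariance checks: H(RA) = D H(A) D^T.
.orbitalRotationMatrix <- function(index, R) {
  n <- nrow(index)
  D <- matrix(0, n, n)
  Dl <- list()
  pos <- 1L
  while (pos <= n) {
    l <- index$l[pos]
    d <- 2L * l + 1L
    key <- as.character(l)
    if (is.null(Dl[[key]])) Dl[[key]] <- wignerDReal(l, R)
    D[pos:(pos + d - 1L), pos:(pos + d - 1L)] <- Dl[[key]]
    pos <- pos + d
  }
  D
}
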