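## Irreducible-representation algebra for Hamiltonian pair blocks and the
## equivariant linear map from features to blocks, plus assembly of the full
## symmetric matrix.

#' Decompose an orbital sub-matrix into irreducible components
#'
#' Exact linear change of basis from the uncoupled |l m>|l' m'> product basis
#' of a shell-pair block to the coupled angular (irrep) basis |lambda mu>,
#' effected through real Clebsch-Gordan coefficients. The transform is
#' orthonormal, so the sum of squares is preserved (Parseval).
#'
#' @param block Numeric matrix `(2 la + 1) x (2 lb + 1)`.
#' @param la,lb Angular momenta of the row/column shells.
#' @return Named list over `lambda = abs(la-lb) .. la+lb` of numeric
#'   mu-vectors of length `2 lambda + 1`.
#' @export
decomposeToIrreps <- function(block, la, lb) {
  if (!all(dim(block) == c(2 * la + 1, 2 * lb + 1)))
    stop("shape error: block dimensions do not match (la, lb)")
  out <- list()
  for (lambda in abs(la - lb):(la + lb)) {
    W <- cgReal(la, lb, lambda)
    out[[as.character(lambda)]] <-
      vapply(seq_len(2 * lambda + 1),
             function(mu) sum(W[mu, , ] * block), numeric(1))
  }
  out
}

#' Recompose an orbital sub-matrix from irreducible components
#'
#' Exact inverse of [decomposeToIrreps()].
#'
#' @param irreps Named list over lambda (as characters) of mu-vectors; the
#'   complete lambda set `abs(la-lb) .. la+lb` must be present (missing
#'   entries raise an incomplete-data error; explicitly zero vectors are
#'   fine).
#' @param la,lb Angular momenta of the row/column shells.
#' @return Numeric matrix `(2 la + 1) x (2 lb + 1)`.
#' @export
recomposeFromIrreps <- function(irreps, la, lb) {
  B <- matrix(0, 2 * la + 1, 2 * lb + 1)
  for (lambda in abs(la - lb):(la + lb)) {
    v <- irreps[[as.character(lambda)]]
    if (is.null(v))
      stop("incomplete-data error: missing lambda = ", lambda, " channel")
    W <- cgReal(la, lb, lambda)
    for (mu in seq_len(2 * lambda + 1)) B <- B + v[mu] * W[mu, , ]
  }
  B
}

## ---- target block enumeration -------------------------------------------

#' Enumerate the target Hamiltonian blocks of a layout
#'
#' Lists every independent irreducible target component: on-site shell-pair
#' blocks per element, permutation-adapted (tau = s/a) same-species off-site
#' blocks, and species-ordered hetero blocks, each with its SO(3) order
#' lambda and parity sigma = (-1)^(la + lb + lambda).
#'
#' @param layout A [BasisLayout-class].
#' @param elements Element set of the model.
#' @return data.frame with columns key, tau, sigma, lambda, a, b, la, lb,
#'   group, wname.
#' @export
targetBlocks <- function(layout, elements = names(.elementZ)) {
  rows <- list()
  add <- function(key, tau, sigma, lambda, a, b, la, lb) {
    group <- sprintf("%s/%s/%+d|%d", key, tau, sigma, lambda)
    rows[[length(rows) + 1L]] <<-
      data.frame(key = key, tau = tau, sigma = sigma, lambda = lambda,
                 a = a, b = b, la = la, lb = lb, group = group,
                 wname = paste0(group, "#", a, "-", b))
  }
  for (el in elements) {
    sh <- elementShells(layout, el)
    for (a in seq_len(nrow(sh))) for (b in a:nrow(sh)) {
      la <- sh$l[a]; lb <- sh$l[b]
      for (lambda in abs(la - lb):(la + lb)) {
        if (a == b && lambda %% 2 == 1) next  # symmetric square block
        add(paste0("on|", el), "0", (-1)^(la + lb + lambda), lambda, a, b, la, lb)
      }
    }
  }
  ord <- elements[.speciesOrder(elements)]
  for (e1i in seq_along(ord)) for (e2i in e1i:length(ord)) {
    e1 <- ord[e1i]; e2 <- ord[e2i]
    sh1 <- elementShells(layout, e1); sh2 <- elementShells(layout, e2)
    key <- paste(e1, e2, sep = "|")
    if (e1 == e2) {
      for (a in seq_len(nrow(sh1))) for (b in a:nrow(sh1)) {
        la <- sh1$l[a]; lb <- sh1$l[b]
        for (lambda in abs(la - lb):(la + lb)) {
          sg <- (-1)^(la + lb + lambda)
          if (a < b) {
            add(key, "s", sg, lambda, a, b, la, lb)
            add(key, "a", sg, lambda, a, b, la, lb)
          } else {
            add(key, if (lambda %% 2 == 0) "s" else "a", sg, lambda, a, b, la, lb)
          }
        }
      }
    } else {
      for (a in seq_len(nrow(sh1))) for (b in seq_len(nrow(sh2))) {
        la <- sh1$l[a]; lb <- sh2$l[b]
        for (lambda in abs(la - lb):(la + lb))
          add(key, "0", (-1)^(la + lb + lambda), lambda, a, b, la, lb)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Initialize a zero weight set for a layout/feature spec
#'
#' One weight vector per target block, with length equal to the number of
#' matching feature channels of its symmetry group. Intercepts are fixed to
#' zero.
#'
#' @param features A [TwoCenterFeatures-class] (defines the channel counts).
#' @param layout A [BasisLayout-class].
#' @return Named list of zero weight vectors keyed by `wname`.
#' @export
zeroWeights <- function(features, layout) {
  tb <- targetBlocks(layout, features@elements)
  w <- list()
  for (r in seq_len(nrow(tb))) {
    ch <- features@channels[[tb$group[r]]]
    nq <- if (is.null(ch)) {
      ## group absent from this particular feature set (e.g. no such pairs);
      ## fall back to enumerating channels directly
      sp0 <- do.call(radialBasisSpec, features@spec[c("nMax", "lMax",
        "gaussianWidth", "cutoff", "taperWidth", "lambdaMax")])
      tab <- if (startsWith(tb$key[r], "on|"))
        .onChannels(sp0, features@elements, tb$lambda[r], tb$sigma[r])
      else .offChannels(sp0, features@elements, tb$lambda[r], tb$sigma[r])
      if (!is.null(tab) && tb$tau[r] %in% c("s", "a")) {
        keep <- tab$type != "pair" |
          (tb$lambda[r] %% 2 == (if (tb$tau[r] == "s") 0 else 1))
        tab <- tab[keep, , drop = FALSE]
      }
      if (is.null(tab)) 0L else nrow(tab)
    } else nrow(ch)
    w[[tb$wname[r]]] <- numeric(nq)
  }
  w
}

## ---- prediction ----------------------------------------------------------

#' Predict irreducible Hamiltonian blocks from features
#'
#' Linear map H_ij^{p tau lambda mu} = sum_q w_q^{p tau lambda}
#' xi_q^{tau lambda mu}(A_ij); intercepts are zero.
#'
#' @param features A [TwoCenterFeatures-class].
#' @param weights Named weight list (see [zeroWeights()]).
#' @param layout A [BasisLayout-class].
#' @return Irrep-block container: list `[[group]][[block]]` of matrices
#'   (group pair row x mu).
#' @export
predictBlocks <- function(features, weights, layout) {
  tb <- targetBlocks(layout, features@elements)
  irreps <- list()
  for (r in seq_len(nrow(tb))) {
    g <- tb$group[r]
    arr <- features@groups[[g]]
    if (is.null(arr)) next
    w <- weights[[tb$wname[r]]]
    if (is.null(w)) stop("configuration error: no weights for ", tb$wname[r])
    if (length(w) != dim(arr)[2])
      stop("configuration error: channel mismatch for ", tb$wname[r],
           " (", length(w), " weights vs ", dim(arr)[2], " channels)")
    d <- dim(arr)
    pred <- matrix(matrix(aperm(arr, c(1, 3, 2)), d[1] * d[3], d[2]) %*% w,
                   d[1], d[3])
    blk <- paste0(tb$a[r], "-", tb$b[r])
    if (is.null(irreps[[g]])) irreps[[g]] <- list()
    irreps[[g]][[blk]] <- pred
  }
  attr(irreps, "layout") <- layout
  irreps
}

## orbital rows of (atom, shell)
.shellSlice <- function(index, atom, shell) {
  index$index[index$atom == atom & index$shell == shell]
}

## fetch the mu-vector of (group, block) for the q-th row of the group
.irrepRow <- function(irreps, group, blk, q, lambda) {
  g <- irreps[[group]]
  if (is.null(g) || is.null(g[[blk]])) return(numeric(2 * lambda + 1))
  g[[blk]][q, ]
}

#' Assemble the full effective Hamiltonian from irrep blocks
#'
#' Places every per-pair sub-matrix recomposed from its irreducible
#' components, fills (j, i) with the transpose of (i, j), and leaves blocks
#' of pairs beyond the cutoff exactly zero.
#'
#' @param irreps Output of [predictBlocks()] (or a target decomposition from
#'   [decomposeStructure()]).
#' @param geometry A [MolecularGeometry-class].
#' @param layout A [BasisLayout-class].
#' @param features The [TwoCenterFeatures-class] the irreps are aligned to.
#' @return An [EffectiveHamiltonian-class].
#' @export
assembleHamiltonian <- function(irreps, geometry, layout, features) {
  index <- buildOrbitalIndex(geometry, layout)
  n <- nrow(index)
  H <- matrix(0, n, n)
  pairs <- features@pairs
  syms <- atomSymbols(geometry)
  spec <- features@spec
  rowOfKey <- split(seq_len(nrow(pairs)), pairs$key)
  for (key in names(rowOfKey)) {
    prows <- rowOfKey[[key]]
    sp <- strsplit(key, "\\|")[[1]]
    onsite <- sp[1] == "on"
    for (q in seq_along(prows)) {
      p <- prows[q]
      i <- pairs$i[p]; j <- pairs$j[p]
      if (onsite) {
        el <- sp[2]
        sh <- elementShells(layout, el)
        for (a in seq_len(nrow(sh))) for (b in a:nrow(sh)) {
          la <- sh$l[a]; lb <- sh$l[b]
          Tl <- list()
          for (lambda in abs(la - lb):(la + lb)) {
            v <- numeric(2 * lambda + 1)
            if (!(a == b && lambda %% 2 == 1)) {
              g <- sprintf("%s/0/%+d|%d", key, (-1)^(la + lb + lambda), lambda)
              v <- .irrepRow(irreps, g, paste0(a, "-", b), q, lambda)
            }
            Tl[[as.character(lambda)]] <- v
          }
          B <- recomposeFromIrreps(Tl, la, lb)
          ra <- .shellSlice(index, i, a); rb <- .shellSlice(index, i, b)
          H[ra, rb] <- H[ra, rb] + B
          if (a != b) H[rb, ra] <- H[rb, ra] + t(B)
        }
      } else if (sp[1] == sp[2]) {
        sh <- elementShells(layout, sp[1])
        for (a in seq_len(nrow(sh))) for (b in a:nrow(sh)) {
          la <- sh$l[a]; lb <- sh$l[b]
          Ua <- list(); Va <- list()
          for (lambda in abs(la - lb):(la + lb)) {
            s <- (-1)^(la + lb + lambda)
            sg <- sprintf("%+d|%d", s, lambda)
            blk <- paste0(a, "-", b)
            if (a < b) {
              Ts <- .irrepRow(irreps, paste0(key, "/s/", sg), blk, q, lambda)
              Ta <- .irrepRow(irreps, paste0(key, "/a/", sg), blk, q, lambda)
              Ua[[as.character(lambda)]] <- (Ts + Ta) / sqrt(2)
              Va[[as.character(lambda)]] <- s * (Ts - Ta) / sqrt(2)
            } else {
              tau <- if (lambda %% 2 == 0) "s" else "a"
              Ua[[as.character(lambda)]] <-
                .irrepRow(irreps, paste0(key, "/", tau, "/", sg), blk, q, lambda)
            }
          }
          ri_a <- .shellSlice(index, i, a); rj_b <- .shellSlice(index, j, b)
          B <- recomposeFromIrreps(Ua, la, lb)
          H[ri_a, rj_b] <- H[ri_a, rj_b] + B
          if (a != b) {
            ri_b <- .shellSlice(index, i, b); rj_a <- .shellSlice(index, j, a)
            Bba <- recomposeFromIrreps(Va, lb, la)
            H[ri_b, rj_a] <- H[ri_b, rj_a] + Bba
          }
        }
      } else {
        ## hetero pair: center = first (heavier) species of the key
        ctr <- if (syms[i] == sp[1]) i else j
        oth <- if (ctr == i) j else i
        sh1 <- elementShells(layout, sp[1]); sh2 <- elementShells(layout, sp[2])
        for (a in seq_len(nrow(sh1))) for (b in seq_len(nrow(sh2))) {
          la <- sh1$l[a]; lb <- sh2$l[b]
          Tl <- list()
          for (lambda in abs(la - lb):(la + lb)) {
            g <- sprintf("%s/0/%+d|%d", key, (-1)^(la + lb + lambda), lambda)
            Tl[[as.character(lambda)]] <-
              .irrepRow(irreps, g, paste0(a, "-", b), q, lambda)
          }
          B <- recomposeFromIrreps(Tl, la, lb)
          rc <- .shellSlice(index, ctr, a); ro <- .shellSlice(index, oth, b)
          H[rc, ro] <- H[rc, ro] + B
        }
      }
    }
  }
  ## each off-site pair filled one orientation; mirror to the other
  atomOf <- index$atom
  sameAtom <- outer(atomOf, atomOf, "==")
  Hoff <- H; Hoff[sameAtom] <- 0
  H[!sameAtom] <- 0
  H <- H + Hoff + t(Hoff)
  asym <- max(abs(H - t(H)))
  if (asym > 1e-10) stop("internal error: assembled matrix asymmetry ", asym)
  H <- (H + t(H)) / 2
  new("EffectiveHamiltonian", matrix = H, index = index)
}

## ---- target decomposition (inverse of assembly) --------------------------

## irreps from the lambda-list of a decomposed block
.blockIrreps <- function(H, index, atomR, shellR, atomC, shellC, la, lb) {
  B <- H[.shellSlice(index, atomR, shellR), .shellSlice(index, atomC, shellC),
         drop = FALSE]
  decomposeToIrreps(matrix(B, 2 * la + 1, 2 * lb + 1), la, lb)
}

#' Decompose a full symmetric Hamiltonian into aligned target components
#'
#' Inverse of [assembleHamiltonian()]: extracts, for every canonical pair of
#' a feature set, the permutation-adapted irreducible components that the
#' linear model predicts. With `adjoint = TRUE` the off-site (and on-site
#' off-diagonal shell) components are doubled, which makes the function the
#' exact adjoint of assembly - used for backpropagating matrix-level
#' gradients onto the components.
#'
#' @param H Numeric symmetric matrix (or [EffectiveHamiltonian-class]).
#' @param geometry A [MolecularGeometry-class].
#' @param layout A [BasisLayout-class].
#' @param features The [TwoCenterFeatures-class] defining pair alignment.
#' @param adjoint Logical; see above.
#' @return Irrep container in the same shape as [predictBlocks()] output.
#' @export
decomposeStructure <- function(H, geometry, layout, features, adjoint = FALSE) {
  if (is(H, "EffectiveHamiltonian")) H <- hamiltonianMatrix(H)
  index <- buildOrbitalIndex(geometry, layout)
  pairs <- features@pairs
  syms <- atomSymbols(geometry)
  irreps <- list()
  put <- function(group, blk, q, nrows, v) {
    lambda <- length(v) %/% 2L
    if (is.null(irreps[[group]])) irreps[[group]] <<- list()
    if (is.null(irreps[[group]][[blk]]))
      irreps[[group]][[blk]] <<- matrix(0, nrows, length(v))
    irreps[[group]][[blk]][q, ] <<- v
  }
  rowOfKey <- split(seq_len(nrow(pairs)), pairs$key)
  for (key in names(rowOfKey)) {
    prows <- rowOfKey[[key]]
    nrows <- length(prows)
    sp <- strsplit(key, "\\|")[[1]]
    for (q in seq_along(prows)) {
      p <- prows[q]
      i <- pairs$i[p]; j <- pairs$j[p]
      if (sp[1] == "on") {
        sh <- elementShells(layout, sp[2])
        for (a in seq_len(nrow(sh))) for (b in a:nrow(sh)) {
          la <- sh$l[a]; lb <- sh$l[b]
          Tl <- .blockIrreps(H, index, i, a, i, b, la, lb)
          fac <- if (adjoint && a < b) 2 else 1
          for (lambda in abs(la - lb):(la + lb)) {
            if (a == b && lambda %% 2 == 1) next
            g <- sprintf("%s/0/%+d|%d", key, (-1)^(la + lb + lambda), lambda)
            put(g, paste0(a, "-", b), q, nrows,
                fac * Tl[[as.character(lambda)]])
          }
        }
      } else if (sp[1] == sp[2]) {
        sh <- elementShells(layout, sp[1])
        fac <- if (adjoint) 2 else 1
        for (a in seq_len(nrow(sh))) for (b in a:nrow(sh)) {
          la <- sh$l[a]; lb <- sh$l[b]
          U <- .blockIrreps(H, index, i, a, j, b, la, lb)
          V <- if (a < b) .blockIrreps(H, index, i, b, j, a, lb, la) else NULL
          for (lambda in abs(la - lb):(la + lb)) {
            s <- (-1)^(la + lb + lambda)
            sg <- sprintf("%+d|%d", s, lambda)
            blk <- paste0(a, "-", b)
            u <- U[[as.character(lambda)]]
            if (a < b) {
              v <- V[[as.character(lambda)]]
              put(paste0(key, "/s/", sg), blk, q, nrows, fac * (u + s * v) / sqrt(2))
              put(paste0(key, "/a/", sg), blk, q, nrows, fac * (u - s * v) / sqrt(2))
            } else {
              tau <- if (lambda %% 2 == 0) "s" else "a"
              put(paste0(key, "/", tau, "/", sg), blk, q, nrows, fac * u)
            }
          }
        }
      } else {
        ctr <- if (syms[i] == sp[1]) i else j
        oth <- if (ctr == i) j else i
        sh1 <- elementShells(layout, sp[1]); sh2 <- elementShells(layout, sp[2])
        fac <- if (adjoint) 2 else 1
        for (a in seq_len(nrow(sh1))) for (b in seq_len(nrow(sh2))) {
          la <- sh1$l[a]; lb <- sh2$l[b]
          Tl <- .blockIrreps(H, index, ctr, a, oth, b, la, lb)
          for (lambda in abs(la - lb):(la + lb)) {
            g <- sprintf("%s/0/%+d|%d", key, (-1)^(la + lb + lambda), lambda)
            put(g, paste0(a, "-", b), q, nrows, fac * Tl[[as.character(lambda)]])
          }
        }
      }
    }
  }
  attr(irreps, "layout") <- layout
  irreps
}

#' Predict the effective Hamiltonian of a molecule
#'
#' Convenience wrapper: [predictBlocks()] followed by
#' [assembleHamiltonian()].
#'
#' @param features A [TwoCenterFeatures-class].
#' @param weights Named weight list.
#' @param geometry A [MolecularGeometry-class].
#' @param layout A [BasisLayout-class].
#' @return An [EffectiveHamiltonian-class].
#' @export
predictHamiltonian <- function(features, weights, geometry, layout) {
  irreps <- predictBlocks(features, weights, layout)
  assembleHamiltonian(irreps, geometry, layout, features)
}

#' Loewdin symmetric orthogonalization of a Hamiltonian
#'
#' Returns `S^{-1/2} H S^{-1/2}`; its ordinary eigenvalues equal the
#' generalized eigenvalues of the pencil (H, S).
#'
#' @param hamiltonian Dense symmetric matrix.
#' @param overlap Dense symmetric positive-definite overlap matrix.
#' @return Dense symmetric matrix.
#' @export
lowdinOrthogonalize <- function(hamiltonian, overlap) {
  es <- eigen((overlap + t(overlap)) / 2, symmetric = TRUE)
  if (min(es$values) <= 1e-12 * max(abs(es$values)))
    stop("numerical error: overlap not positive-definite (smallest eigenvalue ",
         format(min(es$values)), ")")
  Sinv <- es$vectors %*% (t(es$vectors) / sqrt(es$values))
  M <- Sinv %*% ((hamiltonian + t(hamiltonian)) / 2) %*% Sinv
  (M + t(M)) / 2
}

## ---- precompiled linear assembly operator --------------------------------
## The map (weights -> assembled Hamiltonian) is linear; for iterative
## indirect training it is precompiled per structure into a sparse operator
## A (n_orb^2 x n_components) plus per-group design matrices, so that one
## objective evaluation is a couple of small matrix products.

.assemblyOperator <- function(features, layout, geometry) {
  index <- buildOrbitalIndex(geometry, layout)
  n <- nrow(index)
  pairs <- features@pairs
  syms <- atomSymbols(geometry)
  tb <- targetBlocks(layout, features@elements)
  rowOfKey <- split(seq_len(nrow(pairs)), pairs$key)
  ## segment table
  segs <- list(); off <- 0L
  for (r in seq_len(nrow(tb))) {
    g <- tb$group[r]
    if (is.null(features@groups[[g]])) next
    nr <- dim(features@groups[[g]])[1]
    if (nr == 0) next
    len <- nr * (2L * tb$lambda[r] + 1L)
    segs[[tb$wname[r]]] <- list(offset = off, len = len, group = g,
                                nrows = nr, lambda = tb$lambda[r])
    off <- off + len
  }
  nT <- off
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  emit <- function(wname, q, lambda, Wc, rowsIdx, colsIdx, fac) {
    ## component (q, mu) with coefficient fac * Wc[mu, m1, m2]
    ## onto entries (rowsIdx[m1], colsIdx[m2]) of H
    sg <- segs[[wname]]
    if (is.null(sg)) return()
    nr <- sg$nrows
    for (mu in seq_len(2L * lambda + 1L)) {
      comp <- sg$offset + (mu - 1L) * nr + q
      Wm <- matrix(Wc[mu, , ], length(rowsIdx), length(colsIdx))
      nz <- which(Wm != 0, arr.ind = TRUE)
      if (!nrow(nz)) next
      ent <- (colsIdx[nz[, 2]] - 1L) * n + rowsIdx[nz[, 1]]
      ti <<- c(ti, ent); tj <<- c(tj, rep.int(comp, nrow(nz)))
      tx <<- c(tx, fac * Wm[nz])
    }
  }
  for (key in names(rowOfKey)) {
    prows <- rowOfKey[[key]]
    sp <- strsplit(key, "\\|")[[1]]
    for (q in seq_along(prows)) {
      p <- prows[q]
      i <- pairs$i[p]; j <- pairs$j[p]
      if (sp[1] == "on") {
        sh <- elementShells(layout, sp[2])
        for (a in seq_len(nrow(sh))) for (b in a:nrow(sh)) {
          la <- sh$l[a]; lb <- sh$l[b]
          ra <- .shellSlice(index, i, a); rb <- .shellSlice(index, i, b)
          for (lambda in abs(la - lb):(la + lb)) {
            if (a == b && lambda %% 2 == 1) next
            wn <- sprintf("%s/0/%+d|%d#%d-%d", key,
                          (-1)^(la + lb + lambda), lambda, a, b)
            W <- cgReal(la, lb, lambda)
            emit(wn, q, lambda, W, ra, rb, 1)
            if (a != b) emit(wn, q, lambda, aperm(W, c(1, 3, 2)), rb, ra, 1)
          }
        }
      } else if (sp[1] == sp[2]) {
        sh <- elementShells(layout, sp[1])
        for (a in seq_len(nrow(sh))) for (b in a:nrow(sh)) {
          la <- sh$l[a]; lb <- sh$l[b]
          ri_a <- .shellSlice(index, i, a); rj_b <- .shellSlice(index, j, b)
          for (lambda in abs(la - lb):(la + lb)) {
            s <- (-1)^(la + lb + lambda)
            W <- cgReal(la, lb, lambda)
            Wt <- aperm(W, c(1, 3, 2))
            blk <- sprintf("#%d-%d", a, b)
            if (a < b) {
              ri_b <- .shellSlice(index, i, b); rj_a <- .shellSlice(index, j, a)
              Wba <- cgReal(lb, la, lambda)
              Wbat <- aperm(Wba, c(1, 3, 2))
              wns <- sprintf("%s/s/%+d|%d%s", key, s, lambda, blk)
              wna <- sprintf("%s/a/%+d|%d%s", key, s, lambda, blk)
              for (wn in c(wns, wna)) {
                sgn <- if (wn == wns) 1 else -1
                ## U = (Ts + Ta)/sqrt2 at (i:a, j:b) (+ transpose)
                emit(wn, q, lambda, W, ri_a, rj_b, 1 / sqrt(2))
                emit(wn, q, lambda, Wt, rj_b, ri_a, 1 / sqrt(2))
                ## V = s (Ts - Ta)/sqrt2 at (i:b, j:a) (+ transpose)
                emit(wn, q, lambda, Wba, ri_b, rj_a, sgn * s / sqrt(2))
                emit(wn, q, lambda, Wbat, rj_a, ri_b, sgn * s / sqrt(2))
              }
            } else {
              tau <- if (lambda %% 2 == 0) "s" else "a"
              wn <- sprintf("%s/%s/%+d|%d%s", key, tau, s, lambda, blk)
              emit(wn, q, lambda, W, ri_a, rj_b, 1)
              emit(wn, q, lambda, Wt, rj_b, ri_a, 1)
            }
          }
        }
      } else {
        ctr <- if (syms[i] == sp[1]) i else j
        oth <- if (ctr == i) j else i
        sh1 <- elementShells(layout, sp[1]); sh2 <- elementShells(layout, sp[2])
        for (a in seq_len(nrow(sh1))) for (b in seq_len(nrow(sh2))) {
          la <- sh1$l[a]; lb <- sh2$l[b]
          rc <- .shellSlice(index, ctr, a); ro <- .shellSlice(index, oth, b)
          for (lambda in abs(la - lb):(la + lb)) {
            wn <- sprintf("%s/0/%+d|%d#%d-%d", key,
                          (-1)^(la + lb + lambda), lambda, a, b)
            W <- cgReal(la, lb, lambda)
            emit(wn, q, lambda, W, rc, ro, 1)
            emit(wn, q, lambda, aperm(W, c(1, 3, 2)), ro, rc, 1)
          }
        }
      }
    }
  }
  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n * n, max(nT, 1L)))
  designs <- lapply(features@groups, .designMatrix)
  list(A = A, segs = segs, designs = designs, n = n, index = index)
}

## forward: weights (named list) -> dense symmetric H via the operator
.operatorHamiltonian <- function(op, weights) {
  Tv <- numeric(ncol(op$A))
  for (wn in names(op$segs)) {
    sg <- op$segs[[wn]]
    w <- weights[[wn]]
    if (is.null(w)) stop("configuration error: no weights for ", wn)
    Tv[sg$offset + seq_len(sg$len)] <- op$designs[[sg$group]] %*% w
  }
  matrix(as.numeric(op$A %*% Tv), op$n, op$n)
}

## adjoint: matrix-level gradient -> per-weight gradients (named list)
.operatorGradient <- function(op, G) {
  gT <- as.numeric(Matrix::crossprod(op$A, as.numeric(G)))
  out <- list()
  for (wn in names(op$segs)) {
    sg <- op$segs[[wn]]
    out[[wn]] <- as.numeric(crossprod(op$designs[[sg$group]],
                                      gT[sg$offset + seq_len(sg$len)]))
  }
  out
}
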