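## Two-center, one-neighbor symmetry-adapted descriptors xi^{tau lambda mu}.
## Pipeline: pairDensity -> neighborDensity -> coupleFeatures (directed pairs)
## -> symmetrizePairChannels (permutation-adapted channels, canonical pairs).

#' Radial basis / feature hyperparameter specification
#'
#' Defines the discretization of the pair density: `nMax` Gaussian-bump
#' radial functions with centers uniformly spaced on (0, cutoff], spherical
#' harmonics up to `lMax`, and a smooth cosine-squared cutoff taper over the
#' outer `taperWidth` Angstrom. `gaussianWidth` is the density smearing; it
#' widens the radial bumps in quadrature with their spacing.
#'
#' @param nMax Number of radial functions (>= 1).
#' @param lMax Maximum angular momentum of the density expansion (>= 0).
#' @param gaussianWidth Density smearing width, Angstrom.
#' @param cutoff Feature cutoff radius, Angstrom (> 0).
#' @param taperWidth Width of the smooth cutoff switch, Angstrom.
#' @param lambdaMax Highest tensor order kept when coupling channels;
#'   defaults to `2 * lMax` and is capped at fit time by what the target
#'   blocks need (2 for an s/p minimal basis).
#' @return List with class `RadialBasisSpec`.
#' @export
radialBasisSpec <- function(nMax = 6L, lMax = 4L, gaussianWidth = 0.2,
                            cutoff = 4.5, taperWidth = 0.5,
                            lambdaMax = NULL) {
  stopifnot(nMax >= 1, lMax >= 0, cutoff > 0, taperWidth > 0,
            gaussianWidth > 0)
  if (is.null(lambdaMax)) lambdaMax <- 2L * lMax
  spacing <- cutoff / nMax
  structure(list(nMax = as.integer(nMax), lMax = as.integer(lMax),
                 gaussianWidth = gaussianWidth, cutoff = cutoff,
                 taperWidth = taperWidth, lambdaMax = as.integer(lambdaMax),
                 centers = seq_len(nMax) * spacing,
                 sigma = sqrt((spacing / sqrt(2))^2 + gaussianWidth^2),
                 functionalForm = "gaussian_bumps"),
            class = "RadialBasisSpec")
}

## radial functions: matrix length(r) x nMax
.radialEval <- function(spec, r) {
  outer(r, spec$centers, function(rr, c0) exp(-(rr - c0)^2 / (2 * spec$sigma^2)))
}

## C1 cutoff switch: 1 inside, cos^2 taper on the outer taperWidth, 0 beyond
.cutoffTaper <- function(spec, r) {
  r0 <- spec$cutoff - spec$taperWidth
  f <- ifelse(r <= r0, 1,
       ifelse(r >= spec$cutoff, 0,
              cos(pi / 2 * (r - r0) / spec$taperWidth)^2))
  f
}

#' Pair density coefficients
#'
#' Evaluates c_nlm(A_ij) = f_cut(r) R_n(r) Y_lm(r_hat) for both orientations
#' of every off-site pair. The coefficients specify the position of atom j
#' relative to atom i, discretized on the radial basis and real spherical
#' harmonics; they vanish smoothly at the cutoff.
#'
#' @param geometry A [MolecularGeometry-class].
#' @param pairs Pair list from [neighborPairs()] built with `spec$cutoff`.
#' @param spec A [radialBasisSpec()].
#' @return List with `dirs` (data.frame of directed pairs: ctr, nbr, r) and
#'   `coeff`, a list over l = 0..lMax of arrays (directed pair, n, m).
#' @export
pairDensity <- function(geometry, pairs, spec) {
  off <- pairs[!pairs$onsite, , drop = FALSE]
  if (nrow(off) > 0 && any(off$r < 1e-8))
    stop("degenerate geometry: coincident distinct atoms")
  xyz <- coordinates(geometry)
  if (nrow(off) > 0) {
    dirs <- data.frame(ctr = c(off$i, off$j), nbr = c(off$j, off$i),
                       pairRow = rep(which(!pairs$onsite), 2),
                       r = c(off$r, off$r))
    v <- xyz[dirs$nbr, , drop = FALSE] - xyz[dirs$ctr, , drop = FALSE]
  } else {
    dirs <- data.frame(ctr = integer(), nbr = integer(),
                       pairRow = integer(), r = numeric())
    v <- matrix(0, 0, 3)
  }
  nd <- nrow(dirs)
  rad <- if (nd) .radialEval(spec, dirs$r) * .cutoffTaper(spec, dirs$r) else
    matrix(0, 0, spec$nMax)
  coeff <- vector("list", spec$lMax + 1L)
  for (l in 0:spec$lMax) {
    Y <- if (nd) realSphericalHarmonics(l, v) else matrix(0, 0, 2 * l + 1)
    arr <- array(0, c(nd, spec$nMax, 2L * l + 1L))
    for (n in seq_len(spec$nMax)) arr[, n, ] <- rad[, n] * Y
    coeff[[l + 1L]] <- arr
  }
  list(dirs = dirs, coeff = coeff, spec = spec)
}

#' Neighbor density coefficients
#'
#' Sums pair-density coefficients over all neighbors of each center within
#' the cutoff, resolved by neighbor species:
#' c_nlm(A_i; s) = sum_{j in s} c_nlm(A_ij).
#'
#' @param pairDensity Output of [pairDensity()].
#' @param pairs The pair list the density was built from.
#' @param geometry The same [MolecularGeometry-class].
#' @param elements Element set to resolve neighbor species over.
#' @return Nested list `[[atom]][[species]][[l+1]]`: matrices (n x m).
#' @export
neighborDensity <- function(pairDensity, pairs, geometry,
                            elements = names(.elementZ)) {
  nAtoms <- length(geometry)
  spec <- pairDensity$spec
  dens <- lapply(seq_len(nAtoms), function(a)
    stats::setNames(lapply(elements, function(s)
      lapply(0:spec$lMax, function(l)
        matrix(0, spec$nMax, 2L * l + 1L))), elements))
  dirs <- pairDensity$dirs
  syms <- atomSymbols(geometry)
  for (d in seq_len(nrow(dirs))) {
    a <- dirs$ctr[d]; s <- syms[dirs$nbr[d]]
    for (l in 0:spec$lMax) {
      dens[[a]][[s]][[l + 1L]] <- dens[[a]][[s]][[l + 1L]] +
        matrix(pairDensity$coeff[[l + 1L]][d, , ], spec$nMax, 2L * l + 1L)
    }
  }
  dens
}

## ---- channel enumeration -------------------------------------------------

## off-site channels for a given (lambda, sigma)
.offChannels <- function(spec, elements, lambda, sigma) {
  rows <- list()
  if (sigma == 1 && lambda <= spec$lMax)
    rows[[length(rows) + 1L]] <-
      data.frame(type = "pair", s1 = NA, n1 = NA, l1 = NA,
                 n2 = seq_len(spec$nMax), l2 = lambda)
  for (s1 in elements) for (l1 in 0:spec$lMax) for (l2 in 0:spec$lMax) {
    if (lambda < abs(l1 - l2) || lambda > l1 + l2) next
    if ((-1)^(l1 + l2 + lambda) != sigma) next
    g <- expand.grid(n1 = seq_len(spec$nMax), n2 = seq_len(spec$nMax))
    rows[[length(rows) + 1L]] <-
      data.frame(type = "coupled", s1 = s1, n1 = g$n1, l1 = l1,
                 n2 = g$n2, l2 = l2)
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## on-site channels: both factors are neighbor densities at the same center
.onChannels <- function(spec, elements, lambda, sigma) {
  rows <- list()
  if (lambda == 0 && sigma == 1)
    rows[[length(rows) + 1L]] <-
      data.frame(type = "const", s1 = NA, n1 = NA, l1 = NA,
                 s2 = NA, n2 = NA, l2 = NA)
  if (sigma == 1 && lambda <= spec$lMax)
    for (s2 in elements)
      rows[[length(rows) + 1L]] <-
        data.frame(type = "bare", s1 = NA, n1 = NA, l1 = NA,
                   s2 = s2, n2 = seq_len(spec$nMax), l2 = lambda)
  flat <- expand.grid(s = elements, n = seq_len(spec$nMax), l = 0:spec$lMax,
                      stringsAsFactors = FALSE)
  flat$id <- seq_len(nrow(flat))
  for (i1 in flat$id) for (i2 in flat$id) {
    if (i2 < i1) next
    l1 <- flat$l[i1]; l2 <- flat$l[i2]
    if (lambda < abs(l1 - l2) || lambda > l1 + l2) next
    if ((-1)^(l1 + l2 + lambda) != sigma) next
    if (i1 == i2 && lambda %% 2 == 1) next   # antisymmetric self-coupling is 0
    rows[[length(rows) + 1L]] <-
      data.frame(type = "coupled", s1 = flat$s[i1], n1 = flat$n[i1],
                 l1 = l1, s2 = flat$s[i2], n2 = flat$n[i2], l2 = l2)
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## CG-contract two coefficient matrices A (n1 x 2l1+1), B (n2 x 2l2+1)
## -> array (n1, n2, 2 lambda + 1)
.cgContract <- function(A, B, l1, l2, lambda) {
  W <- cgReal(l1, l2, lambda)
  out <- array(0, c(nrow(A), nrow(B), 2L * lambda + 1L))
  for (mu in seq_len(2L * lambda + 1L))
    out[, , mu] <- A %*% matrix(W[mu, , ], 2L * l1 + 1L, 2L * l2 + 1L) %*% t(B)
  out
}

#' Couple densities into symmetry-adapted two-center features
#'
#' Builds the raw (directed) feature channels: for every directed off-site
#' pair, products of the center's neighbor density with the pair density are
#' contracted with real Clebsch-Gordan coefficients into tensors of order
#' lambda in |l - l'| .. l + l', labeled by the parity sigma =
#' (-1)^(l + l' + lambda); the bare pair-density channels are included as
#' lower-order channels. On-site (i, i) channels couple the neighbor density
#' with itself and include a constant scalar channel.
#'
#' @param neighbor Output of [neighborDensity()].
#' @param pair Output of [pairDensity()].
#' @param spec The [radialBasisSpec()] both were built with.
#' @param geometry The [MolecularGeometry-class].
#' @param pairs The pair list.
#' @param elements Element set fixing the channel list (must be a superset of
#'   the geometry's elements, identical across training structures).
#' @return Raw feature object (list, class `RawTwoCenterFeatures`) with
#'   directed off-site rows; pass to [symmetrizePairChannels()].
#' @export
coupleFeatures <- function(neighbor, pair, spec, geometry, pairs,
                           elements = names(.elementZ)) {
  if (!all(unique(atomSymbols(geometry)) %in% elements))
    stop("configuration error: geometry contains elements outside the model element set")
  if (spec$lambdaMax > 2L * spec$lMax)
    stop("configuration error: lambdaMax exceeds tabulated CG range 2*lMax")
  dirs <- pair$dirs
  syms <- atomSymbols(geometry)
  nd <- nrow(dirs)
  nAtoms <- length(geometry)
  off <- list(); on <- list()
  for (lambda in 0:spec$lambdaMax) for (sigma in c(1, -1)) {
    gk <- sprintf("%+d|%d", sigma, lambda)
    chOff <- .offChannels(spec, elements, lambda, sigma)
    if (!is.null(chOff)) {
      arr <- array(0, c(nd, nrow(chOff), 2L * lambda + 1L))
      off[[gk]] <- list(channels = chOff, values = arr)
    }
    chOn <- .onChannels(spec, elements, lambda, sigma)
    if (!is.null(chOn)) {
      arr <- array(0, c(nAtoms, nrow(chOn), 2L * lambda + 1L))
      on[[gk]] <- list(channels = chOn, values = arr)
    }
  }
  ## fill off-site rows
  for (d in seq_len(nd)) {
    ctr <- dirs$ctr[d]
    for (gk in names(off)) {
      ch <- off[[gk]]$channels
      lambda <- as.integer(sub(".*\\|", "", gk))
      isPair <- ch$type == "pair"
      if (any(isPair)) {
        cp <- matrix(pair$coeff[[lambda + 1L]][d, , ], spec$nMax)
        off[[gk]]$values[d, which(isPair), ] <- cp[ch$n2[isPair], , drop = FALSE]
      }
      cps <- which(ch$type == "coupled")
      if (length(cps)) {
        sub <- ch[cps, ]
        for (grp in split(seq_along(cps), list(sub$s1, sub$l1, sub$l2), drop = TRUE)) {
          s1 <- sub$s1[grp[1]]; l1 <- sub$l1[grp[1]]; l2 <- sub$l2[grp[1]]
          A <- neighbor[[ctr]][[s1]][[l1 + 1L]]
          B <- matrix(pair$coeff[[l2 + 1L]][d, , ], spec$nMax)
          Z <- .cgContract(A, B, l1, l2, lambda)
          idx <- cbind(sub$n1[grp], sub$n2[grp])
          for (mu in seq_len(2L * lambda + 1L))
            off[[gk]]$values[d, cps[grp], mu] <- Z[, , mu][idx]
        }
      }
    }
  }
  ## fill on-site rows
  for (a in seq_len(nAtoms)) {
    for (gk in names(on)) {
      ch <- on[[gk]]$channels
      lambda <- as.integer(sub(".*\\|", "", gk))
      isConst <- ch$type == "const"
      if (any(isConst)) on[[gk]]$values[a, which(isConst), 1] <- 1
      isBare <- which(ch$type == "bare")
      if (length(isBare)) {
        sub <- ch[isBare, ]
        for (k in seq_along(isBare)) {
          on[[gk]]$values[a, isBare[k], ] <-
            neighbor[[a]][[sub$s2[k]]][[lambda + 1L]][sub$n2[k], ]
        }
      }
      cps <- which(ch$type == "coupled")
      if (length(cps)) {
        sub <- ch[cps, ]
        for (grp in split(seq_along(cps),
                          list(sub$s1, sub$l1, sub$s2, sub$l2), drop = TRUE)) {
          s1 <- sub$s1[grp[1]]; l1 <- sub$l1[grp[1]]
          s2 <- sub$s2[grp[1]]; l2 <- sub$l2[grp[1]]
          A <- neighbor[[a]][[s1]][[l1 + 1L]]
          B <- neighbor[[a]][[s2]][[l2 + 1L]]
          Z <- .cgContract(A, B, l1, l2, lambda)
          idx <- cbind(sub$n1[grp], sub$n2[grp])
          for (mu in seq_len(2L * lambda + 1L))
            on[[gk]]$values[a, cps[grp], mu] <- Z[, , mu][idx]
        }
      }
    }
  }
  structure(list(dirs = dirs, off = off, on = on, pairs = pairs,
                 spec = spec, elements = elements,
                 symbols = syms),
            class = "RawTwoCenterFeatures")
}

## canonical species ordering: heavier first
.speciesOrder <- function(s) order(-.elementZ[s])

#' Permutation-symmetrize pair feature channels
#'
#' Collapses the directed raw features onto canonical pairs. Same-species
#' off-site channels are replaced by normalized symmetric (tau = "s") and
#' antisymmetric (tau = "a") combinations under the i <-> j label swap;
#' hetero pairs keep the orientation with the heavier species as the center
#' (tau = "0"); on-site channels pass through unchanged (tau = "0").
#'
#' @param raw A `RawTwoCenterFeatures` from [coupleFeatures()].
#' @return A [TwoCenterFeatures-class].
#' @export
symmetrizePairChannels <- function(raw) {
  pairs <- raw$pairs
  syms <- raw$symbols
  key <- character(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    if (pairs$onsite[p]) key[p] <- paste0("on|", syms[pairs$i[p]])
    else {
      sp <- c(syms[pairs$i[p]], syms[pairs$j[p]])
      key[p] <- paste(sp[.speciesOrder(sp)], collapse = "|")
    }
  }
  pairs$key <- key
  groups <- list(); channels <- list()
  ## on-site groups, per element
  for (el in unique(syms)) {
    rows <- which(pairs$onsite & syms[pairs$i] == el)
    if (!length(rows)) next
    atoms <- pairs$i[rows]
    for (gk in names(raw$on)) {
      gname <- paste0("on|", el, "/0/", gk)
      groups[[gname]] <- raw$on[[gk]]$values[atoms, , , drop = FALSE]
      channels[[gname]] <- raw$on[[gk]]$channels
    }
  }
  ## off-site groups
  offRows <- which(!pairs$onsite)
  if (length(offRows)) {
    dirKey <- paste(raw$dirs$pairRow)
    for (k in unique(pairs$key[offRows])) {
      rows <- offRows[pairs$key[offRows] == k]
      same <- !grepl("\\|", sub("\\|", "", k)) # fallback; computed below anyway
      sp <- strsplit(k, "\\|")[[1]]
      same <- sp[1] == sp[2]
      ## directed indices: orientation 1 = center listed first
      d1 <- integer(length(rows)); d2 <- integer(length(rows))
      for (q in seq_along(rows)) {
        p <- rows[q]
        iEl <- syms[pairs$i[p]]
        ## orientation with center = first species of the key
        cFirst <- if (iEl == sp[1]) pairs$i[p] else pairs$j[p]
        dd <- which(raw$dirs$pairRow == p)
        d1[q] <- dd[raw$dirs$ctr[dd] == cFirst][1]
        d2[q] <- dd[raw$dirs$ctr[dd] != cFirst][1]
      }
      for (gk in names(raw$off)) {
        v1 <- raw$off[[gk]]$values[d1, , , drop = FALSE]
        if (same) {
          v2 <- raw$off[[gk]]$values[d2, , , drop = FALSE]
          gs <- paste0(k, "/s/", gk); ga <- paste0(k, "/a/", gk)
          lambda <- as.integer(sub(".*\\|", "", gk))
          ch <- raw$off[[gk]]$channels
          ## a pure pair channel flips by (-1)^lambda under i <-> j, so it
          ## is identically zero in one of the two permutation channels
          keepS <- ch$type != "pair" | lambda %% 2 == 0
          keepA <- ch$type != "pair" | lambda %% 2 == 1
          groups[[gs]] <- ((v1 + v2) / sqrt(2))[, keepS, , drop = FALSE]
          groups[[ga]] <- ((v1 - v2) / sqrt(2))[, keepA, , drop = FALSE]
          channels[[gs]] <- ch[keepS, , drop = FALSE]
          channels[[ga]] <- ch[keepA, , drop = FALSE]
        } else {
          g0 <- paste0(k, "/0/", gk)
          groups[[g0]] <- v1
          channels[[g0]] <- raw$off[[gk]]$channels
        }
      }
    }
  }
  new("TwoCenterFeatures", pairs = pairs, groups = groups,
      channels = channels, spec = unclass(raw$spec), elements = raw$elements)
}

#' Compute symmetry-adapted features for a molecule
#'
#' Convenience wrapper running [neighborPairs()], [pairDensity()],
#' [neighborDensity()], [coupleFeatures()] and [symmetrizePairChannels()].
#'
#' @inheritParams coupleFeatures
#' @param geometry A [MolecularGeometry-class].
#' @param spec A [radialBasisSpec()].
#' @return A [TwoCenterFeatures-class].
#' @export
moleculeFeatures <- function(geometry, spec, elements = names(.elementZ)) {
  pairs <- neighborPairs(geometry, spec$cutoff)
  pd <- pairDensity(geometry, pairs, spec)
  nd <- neighborDensity(pd, pairs, geometry, elements)
  raw <- coupleFeatures(nd, pd, spec, geometry, pairs, elements)
  symmetrizePairChannels(raw)
}

#' Pairs table of a feature set
#' @param features A [TwoCenterFeatures-class].
#' @return data.frame with columns i, j, r, onsite, key.
#' @export
featurePairs <- function(features) features@pairs

#' Rows of the pair table covered by a feature group
#' @param features A [TwoCenterFeatures-class].
#' @param group Group name ("key/tau/sigma/lambda").
#' @return Integer vector of row indices into `featurePairs(features)`.
#' @export
groupPairRows <- function(features, group) {
  key <- strsplit(group, "/")[[1]][1]
  which(features@pairs$key == key)
}
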