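## Central S4 classes. Light-weight intermediates (pair lists, radial specs,
## gamma kernels, spectra) are plain lists/data.frames documented on their
## constructors.

#' @import methods
NULL

#' MolecularGeometry class
#'
#' Atoms, Cartesian coordinates (Angstrom) and net charge of a molecule.
#' Only neutral closed-shell systems over the supported element set (H, C)
#' are accepted.
#'
#' @slot symbols Character vector of element symbols, one per atom.
#' @slot coordinates Numeric matrix (n x 3), Angstrom.
#' @slot netCharge Integer total charge (elementary charges); 0 in v1.
#' @export
setClass("MolecularGeometry",
  representation(symbols = "character", coordinates = "matrix",
                 netCharge = "integer"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@coordinates) != length(object@symbols))
      msg <- c(msg, "coordinates rows must match number of symbols")
    if (ncol(object@coordinates) != 3)
      msg <- c(msg, "coordinates must have 3 columns")
    if (!all(is.finite(object@coordinates)))
      msg <- c(msg, "coordinates must be finite")
    bad <- setdiff(unique(object@symbols), names(.elementZ))
    if (length(bad))
      msg <- c(msg, paste0("unsupported element(s): ", paste(bad, collapse = ", ")))
    if (length(object@netCharge) != 1 || object@netCharge != 0L)
      msg <- c(msg, "only neutral systems (netCharge = 0) are supported")
    if (length(msg)) msg else TRUE
  })

#' Construct a MolecularGeometry
#'
#' @param symbols Character vector of element symbols (H, C).
#' @param coordinates Numeric n x 3 matrix, Angstrom.
#' @param netCharge Integer net charge (must be 0).
#' @return A [MolecularGeometry-class] object.
#' @export
MolecularGeometry <- function(symbols, coordinates, netCharge = 0L) {
  new("MolecularGeometry", symbols = as.character(symbols),
      coordinates = as.matrix(coordinates), netCharge = as.integer(netCharge))
}

#' @describeIn MolecularGeometry-class Number of atoms.
#' @param x,object A MolecularGeometry.
#' @export
setMethod("length", "MolecularGeometry", function(x) length(x@symbols))

#' Element symbols of a geometry
#' @param object A [MolecularGeometry-class].
#' @return Character vector.
#' @export
atomSymbols <- function(object) object@symbols

#' Cartesian coordinates (Angstrom)
#' @param object A [MolecularGeometry-class].
#' @return Numeric n x 3 matrix.
#' @export
coordinates <- function(object) object@coordinates

#' Atomic numbers Z_A derived from the symbols
#' @param object A [MolecularGeometry-class].
#' @return Integer vector.
#' @export
atomicNumbers <- function(object) unname(.elementZ[object@symbols])

#' Net charge accessor
#' @param object A [MolecularGeometry-class].
#' @return Integer scalar.
#' @export
netCharge <- function(object) object@netCharge

setMethod("show", "MolecularGeometry", function(object) {
  tab <- table(object@symbols)
  cat("MolecularGeometry:", length(object@symbols), "atoms (",
      paste(sprintf("%s%d", names(tab), tab), collapse = " "), "), charge",
      object@netCharge, "\n")
})

#' BasisLayout class
#'
#' Minimal atom-centered orbital layout: an ordered shell list (radial index
#' n, angular momentum l) per element. The default minimal layout assigns H
#' a single 1s orbital and C the 1s, 2s and 2p shells (5 orbitals). Within
#' an atom, orbitals are ordered shell-major with m = -l..+l inside a shell.
#'
#' @slot shells Named list; per element a data.frame with columns `n`, `l`.
#' @export
setClass("BasisLayout", representation(shells = "list"),
  validity = function(object) {
    msg <- character()
    for (el in names(object@shells)) {
      sh <- object@shells[[el]]
      if (!is.data.frame(sh) || !all(c("n", "l") %in% names(sh)))
        msg <- c(msg, paste0("shells for ", el, " must be a data.frame with n, l"))
      else if (any(sh$l < 0)) msg <- c(msg, "l must be >= 0")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a BasisLayout
#'
#' @param shells Named list of data.frames with columns `n` (radial label)
#'   and `l` (angular momentum), one entry per element. Defaults to the
#'   minimal hydrocarbon layout (H: 1s; C: 1s, 2s, 2p).
#' @return A [BasisLayout-class] object.
#' @export
BasisLayout <- function(shells = NULL) {
  if (is.null(shells))
    shells <- list(
      H = data.frame(n = 1L, l = 0L),
      C = data.frame(n = c(1L, 2L, 2L), l = c(0L, 0L, 1L)))
  new("BasisLayout", shells = shells)
}

#' Shells of an element in a layout
#' @param layout A [BasisLayout-class].
#' @param element Element symbol.
#' @return data.frame with columns n, l.
#' @export
elementShells <- function(layout, element) {
  sh <- layout@shells[[element]]
  if (is.null(sh)) stop("BasisLayout has no entry for element ", element)
  sh
}

setMethod("show", "BasisLayout", function(object) {
  cat("BasisLayout:\n")
  for (el in names(object@shells)) {
    sh <- object@shells[[el]]
    cat(" ", el, ":", paste(sprintf("(n=%d,l=%d)", sh$n, sh$l), collapse = " "),
        "->", sum(2L * sh$l + 1L), "orbitals\n")
  }
})

#' TwoCenterFeatures class
#'
#' Symmetry-adapted two-center descriptors xi^{tau lambda mu}(A_ij), grouped
#' by (species-pair key, permutation channel tau, parity sigma, order lambda).
#' Each group holds a 3-d array indexed (pair row, feature channel, mu).
#'
#' @slot pairs data.frame of pairs (i, j, r, key, onsite).
#' @slot groups Named list of feature arrays; names "key|tau|sigma|lambda".
#' @slot channels Named list of per-group channel metadata data.frames.
#' @slot spec List: the radial basis spec the features were built with.
#' @slot elements Character: element set the channel list was enumerated for.
#' @export
setClass("TwoCenterFeatures",
  representation(pairs = "data.frame", groups = "list", channels = "list",
                 spec = "list", elements = "character"))

setMethod("show", "TwoCenterFeatures", function(object) {
  cat("TwoCenterFeatures:", nrow(object@pairs), "pairs,",
      length(object@groups), "symmetry groups, cutoff",
      object@spec$cutoff, "A\n")
})

#' EffectiveHamiltonian class
#'
#' Dense real symmetric effective Hamiltonian (Hartree) in the implicit
#' orthonormal minimal basis, together with the orbital index it is laid
#' out on.
#'
#' @slot matrix Numeric symmetric n x n matrix, Hartree.
#' @slot index data.frame orbital index (atom, shell, l, m).
#' @export
setClass("EffectiveHamiltonian",
  representation(matrix = "matrix", index = "data.frame"),
  validity = function(object) {
    H <- object@matrix
    if (nrow(H) != ncol(H)) return("matrix must be square")
    if (nrow(H) != nrow(object@index)) return("index size must match matrix")
    if (max(abs(H - t(H))) > 1e-10) return("matrix must be symmetric (1e-10)")
    TRUE
  })

#' Hamiltonian matrix accessor
#' @param object An [EffectiveHamiltonian-class] (or MOSolution-compatible object).
#' @return Numeric matrix (Hartree).
#' @export
hamiltonianMatrix <- function(object) object@matrix

#' Orbital index accessor
#' @param object An [EffectiveHamiltonian-class].
#' @return data.frame with one row per orbital.
#' @export
orbitalIndexOf <- function(object) object@index

setMethod("show", "EffectiveHamiltonian", function(object) {
  cat("EffectiveHamiltonian:", nrow(object@matrix), "x", ncol(object@matrix),
      "(Hartree), asymmetry", format(max(abs(object@matrix - t(object@matrix))),
      digits = 3), "\n")
})

#' MOSolution class
#'
#' Eigenpairs of the effective Hamiltonian: molecular-orbital energies
#' (Hartree, ascending) and coefficients, plus the closed-shell occupation.
#'
#' @slot energies Numeric vector, Hartree, ascending.
#' @slot coefficients Orbital x MO matrix with orthonormal columns.
#' @slot nOcc Integer number of doubly occupied MOs.
#' @export
setClass("MOSolution",
  representation(energies = "numeric", coefficients = "matrix", nOcc = "integer"),
  validity = function(object) {
    msg <- character()
    if (is.unsorted(object@energies, strictly = FALSE))
      msg <- c(msg, "energies must be ascending")
    C <- object@coefficients
    if (length(object@energies) != ncol(C))
      msg <- c(msg, "one energy per MO required")
    if (max(abs(crossprod(C) - diag(ncol(C)))) > 1e-8)
      msg <- c(msg, "MO coefficients must be orthonormal (1e-8)")
    if (object@nOcc < 0 || object@nOcc > ncol(C))
      msg <- c(msg, "nOcc out of range")
    if (length(msg)) msg else TRUE
  })

#' MO energies (Hartree)
#' @param object A [MOSolution-class].
#' @return Numeric vector, ascending.
#' @export
moEnergies <- function(object) object@energies

#' MO coefficient matrix
#' @param object A [MOSolution-class].
#' @return Orbital x MO numeric matrix.
#' @export
moCoefficients <- function(object) object@coefficients

#' Number of doubly occupied MOs
#' @param object A [MOSolution-class].
#' @return Integer.
#' @export
nOccupied <- function(object) object@nOcc

setMethod("show", "MOSolution", function(object) {
  cat("MOSolution:", length(object@energies), "MOs,", object@nOcc,
      "occupied; HOMO", format(object@energies[object@nOcc], digits = 6), "Ha\n")
})

#' ExcitationResult class
#'
#' Excitation energies and CIS amplitudes from the simplified Tamm-Dancoff
#' solver.
#'
#' @slot energies Numeric excitation energies Omega_k, eV, ascending.
#' @slot amplitudes Configuration x state matrix of CIS amplitudes X
#'   (orthonormal columns).
#' @slot space data.frame of configurations (columns i, a, primary).
#' @export
setClass("ExcitationResult",
  representation(energies = "numeric", amplitudes = "matrix", space = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (is.unsorted(object@energies)) msg <- c(msg, "energies must be ascending")
    X <- object@amplitudes
    if (ncol(X) != length(object@energies))
      msg <- c(msg, "one amplitude column per state required")
    if (max(abs(crossprod(X) - diag(ncol(X)))) > 1e-8)
      msg <- c(msg, "amplitudes must be orthonormal (1e-8)")
    if (length(msg)) msg else TRUE
  })

#' Excitation energies (eV)
#' @param object An [ExcitationResult-class].
#' @return Numeric vector, ascending.
#' @export
excitationEnergies <- function(object) object@energies

#' CIS amplitudes
#' @param object An [ExcitationResult-class].
#' @return Configuration x state matrix.
#' @export
cisAmplitudes <- function(object) object@amplitudes

#' CI configuration space of a result
#' @param object An [ExcitationResult-class].
#' @return data.frame with columns i (occupied), a (virtual), primary.
#' @export
ciSpace <- function(object) object@space

setMethod("show", "ExcitationResult", function(object) {
  cat("ExcitationResult:", length(object@energies), "states over",
      nrow(object@space), "configurations; Omega_1 =",
      format(object@energies[1], digits = 5), "eV\n")
})

#' TrainedModel class
#'
#' A fitted equivariant Hamiltonian model: per-(block, tau, lambda) weight
#' vectors, the feature/radial spec and basis layout snapshot, the loss
#' configuration, and the recorded loss history.
#'
#' @slot weights Named list of weight vectors, one per target block keyed
#'   "key|tau|sigma|lambda|block".
#' @slot spec List: radial basis spec.
#' @slot layout A [BasisLayout-class].
#' @slot elements Character element set.
#' @slot config List: loss configuration used for training.
#' @slot lossHistory Numeric vector of per-iteration loss values.
#' @export
setClass("TrainedModel",
  representation(weights = "list", spec = "list", layout = "BasisLayout",
                 elements = "character", config = "list",
                 lossHistory = "numeric"))

#' Model weights accessor
#' @param object A [TrainedModel-class].
#' @return Named list of numeric weight vectors.
#' @export
modelWeights <- function(object) object@weights

#' Training loss history
#' @param object A [TrainedModel-class].
#' @return Numeric vector (length 1 for the closed-form direct fit).
#' @export
lossHistory <- function(object) object@lossHistory

setMethod("show", "TrainedModel", function(object) {
  cat("TrainedModel:", length(object@weights), "weight blocks, mode",
      object@config$mode %||% "?", "; final loss",
      format(utils::tail(object@lossHistory, 1), digits = 6), "\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
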