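## Geometry and basis bookkeeping: XYZ I/O, orbital indexing, neighbor pairs.

#' Read a molecular geometry from an XYZ file
#'
#' Standard XYZ: an atom-count line, a comment line (which may carry the net
#' charge as `charge=<int>`), then `symbol x y z` records in Angstrom.
#'
#' @param path Path to the XYZ file.
#' @return A [MolecularGeometry-class].
#' @export
readXYZ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1 || !nzchar(trimws(lines[1])))
    stop("XYZ parse error at line 1: missing atom-count line")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1)
    stop("XYZ parse error at line 1: malformed atom count '", lines[1], "'")
  if (length(lines) < n + 2)
    stop("XYZ parse error: expected ", n + 2, " lines, found ", length(lines))
  charge <- 0L
  m <- regmatches(lines[2], regexec("charge=(-?[0-9]+)", lines[2]))[[1]]
  if (length(m) == 2) charge <- as.integer(m[2])
  symbols <- character(n)
  xyz <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    ln <- n_line <- k + 2L
    parts <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(parts) < 4)
      stop("XYZ parse error at line ", ln, ": expected 'symbol x y z'")
    if (!parts[1] %in% names(.elementZ))
      stop("XYZ parse error at line ", ln, ": unknown element '", parts[1], "'")
    co <- suppressWarnings(as.numeric(parts[2:4]))
    if (any(is.na(co)))
      stop("XYZ parse error at line ", ln, ": non-numeric coordinate")
    symbols[k] <- parts[1]
    xyz[k, ] <- co
  }
  MolecularGeometry(symbols, xyz, charge)
}

#' Write a geometry to an XYZ file
#'
#' @param geometry A [MolecularGeometry-class].
#' @param path Output path.
#' @param comment Comment-line text; the net charge is appended as
#'   `charge=<int>` when nonzero.
#' @return Invisibly, `path`.
#' @export
writeXYZ <- function(geometry, path, comment = "") {
  n <- length(geometry)
  if (netCharge(geometry) != 0L)
    comment <- trimws(paste(comment, sprintf("charge=%d", netCharge(geometry))))
  xyz <- coordinates(geometry)
  rec <- sprintf("%-2s %18.10f %18.10f %18.10f", atomSymbols(geometry),
                 xyz[, 1], xyz[, 2], xyz[, 3])
  writeLines(c(as.character(n), comment, rec), path)
  invisible(path)
}

#' Orbital index of a geometry under a basis layout
#'
#' Maps every (atom, shell, m) triple to a matrix row/column. Orbitals are
#' ordered atom-major, then shell in layout order, then m = -l..+l. The
#' index depends only on the symbols and their order, never on coordinates.
#'
#' @param geometry A [MolecularGeometry-class].
#' @param layout A [BasisLayout-class].
#' @return data.frame with columns atom, element, shell, n, l, m, index.
#' @export
buildOrbitalIndex <- function(geometry, layout) {
  rows <- vector("list", length(geometry))
  idx <- 0L
  for (a in seq_len(length(geometry))) {
    el <- atomSymbols(geometry)[a]
    sh <- elementShells(layout, el)
    part <- do.call(rbind, lapply(seq_len(nrow(sh)), function(s) {
      l <- sh$l[s]
      data.frame(atom = a, element = el, shell = s, n = sh$n[s], l = l,
                 m = seq(-l, l))
    }))
    part$index <- idx + seq_len(nrow(part))
    idx <- idx + nrow(part)
    rows[[a]] <- part
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Total orbital count of a geometry under a layout
#'
#' @inheritParams buildOrbitalIndex
#' @return Integer.
#' @export
countOrbitals <- function(geometry, layout) {
  sum(vapply(atomSymbols(geometry), function(el) {
    sh <- elementShells(layout, el)
    sum(2L * sh$l + 1L)
  }, integer(1)))
}

#' Neighbor pair list within a cutoff
#'
#' Builds the canonical pair list: every on-site pair (i, i), plus every
#' off-site pair (i, j) with i < j whose separation does not exceed the
#' cutoff.
#'
#' @param geometry A [MolecularGeometry-class].
#' @param cutoff Cutoff radius, Angstrom (> 0).
#' @return data.frame with columns i, j, r (Angstrom), onsite; the cutoff is
#'   attached as attribute `cutoff`.
#' @export
neighborPairs <- function(geometry, cutoff) {
  stopifnot(cutoff > 0)
  xyz <- coordinates(geometry)
  n <- nrow(xyz)
  on <- data.frame(i = seq_len(n), j = seq_len(n), r = 0, onsite = TRUE)
  off <- NULL
  if (n > 1) {
    cmb <- utils::combn(n, 2)
    d <- sqrt(rowSums((xyz[cmb[1, ], , drop = FALSE] -
                       xyz[cmb[2, ], , drop = FALSE])^2))
    keep <- d <= cutoff
    if (any(keep))
      off <- data.frame(i = cmb[1, keep], j = cmb[2, keep], r = d[keep],
                        onsite = FALSE)
  }
  out <- rbind(on, off)
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  out
}
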