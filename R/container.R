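## On-disk containers: a JSON "matrix container" holding per-structure
## groups (geometry / hamiltonian / eigenvalues / charges), and model
## serialization with layout, element list and spec embedded for provenance.

## tiny rolling content hash over a serialized object (no external deps;
## 31-bit modular arithmetic stays exact in doubles)
.contentHash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  idx <- seq(1, length(raw), by = max(1L, length(raw) %/% 4096))
  h <- 0
  for (b in as.integer(raw[idx])) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a training-target container
#'
#' Serializes geometries plus targets into a single JSON document with one
#' group per structure (schema: `structures[[k]]$geometry /
#' $hamiltonian / $eigenvalues / $charges`).
#'
#' @param targets A [trainingTarget()].
#' @param path Output path (.json).
#' @return Invisibly, `path`.
#' @export
writeTargetContainer <- function(targets, path) {
  structures <- lapply(seq_along(targets$geometries), function(s) {
    g <- targets$geometries[[s]]
    out <- list(geometry = list(symbols = atomSymbols(g),
                                coordinates = coordinates(g),
                                net_charge = netCharge(g)))
    if (!is.null(targets$hamiltonians))
      out$hamiltonian <- targets$hamiltonians[[s]]
    if (!is.null(targets$eigenvalues))
      out$eigenvalues <- targets$eigenvalues[[s]]
    if (!is.null(targets$charges))
      out$charges <- targets$charges[[s]]
    out
  })
  doc <- list(schema = "equiham-targets-v1", kind = targets$kind,
              n_structures = length(structures), structures = structures)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a training-target container
#'
#' @param path Path written by [writeTargetContainer()].
#' @return A [trainingTarget()].
#' @export
readTargetContainer <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$schema, "equiham-targets-v1"))
    stop("data error: not an equiham target container")
  n <- doc$n_structures
  geoms <- vector("list", n)
  Hs <- list(); eps <- list(); qs <- list()
  asMat <- function(rows)
    do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
  for (k in seq_len(n)) {
    st <- doc$structures[[k]]
    ge <- st$geometry
    geoms[[k]] <- MolecularGeometry(unlist(ge$symbols),
                                    asMat(ge$coordinates),
                                    as.integer(ge$net_charge))
    if (!is.null(st$hamiltonian)) Hs[[k]] <- asMat(st$hamiltonian)
    if (!is.null(st$eigenvalues)) eps[[k]] <- as.numeric(unlist(st$eigenvalues))
    if (!is.null(st$charges)) qs[[k]] <- as.numeric(unlist(st$charges))
  }
  trainingTarget(doc$kind, geoms,
                 hamiltonians = if (length(Hs)) Hs else NULL,
                 eigenvalues = if (length(eps)) eps else NULL,
                 charges = if (length(qs)) qs else NULL)
}

#' Serialize a trained model to a JSON file
#'
#' The file embeds the weights, radial/feature spec, element list, basis
#' layout and loss configuration, plus a content hash for provenance.
#'
#' @param model A [TrainedModel-class].
#' @param path Output path (.json).
#' @return Invisibly, `path`.
#' @export
writeModel <- function(model, path) {
  doc <- list(schema = "equiham-model-v1",
              spec = model@spec[c("nMax", "lMax", "gaussianWidth", "cutoff",
                                  "taperWidth", "lambdaMax")],
              elements = model@elements,
              layout = lapply(model@layout@shells, function(sh)
                list(n = sh$n, l = sh$l)),
              config = model@config,
              weights = model@weights,
              loss_history = model@lossHistory)
  doc$hash <- .contentHash(doc$weights)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a trained model from a JSON file
#'
#' @param path Path written by [writeModel()].
#' @return A [TrainedModel-class].
#' @export
readModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "equiham-model-v1"))
    stop("data error: not an equiham model file")
  shells <- lapply(doc$layout, function(sh)
    data.frame(n = as.integer(sh$n), l = as.integer(sh$l)))
  weights <- lapply(doc$weights, as.numeric)
  new("TrainedModel", weights = weights,
      spec = unclass(do.call(radialBasisSpec, doc$spec)),
      layout = BasisLayout(shells), elements = doc$elements,
      config = as.list(doc$config),
      lossHistory = as.numeric(doc$loss_history))
}
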