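#' Bridge to the bundled RDKit embedding helper
#'
#' SMILES parsing and 3D conformer generation are delegated to RDKit
#' through a bundled batch helper script executed with the system `python`.
#' ETKDG distance-geometry embedding with a fixed random seed is
#' bit-deterministic; UFF supplies the force-field ranking. Responses are
#' memoized per session keyed by (molecule set, n_confs, seed).
#'
#' @name co2screen-rdkit
#' @keywords internal
NULL

.rdkit_cache <- new.env(parent = emptyenv())

.rdkit_script <- function() {
  p <- system.file("python", "rdkit_embed.py", package = "co2screen")
  if (!nzchar(p)) {
    abort_co2("bundled RDKit helper script not found", "backend_error")
  }
  p
}

## molecules: data.frame/list with smiles, id. Returns list of per-molecule
## result lists (ok, error, elements, formal_charges, bonds, conformers).
rdkit_embed_batch <- function(smiles, ids, n_confs = 1, seed = 42) {
  key <- rlang::hash(list(smiles, ids, n_confs, seed))
  hit <- .rdkit_cache[[key]]
  if (!is.null(hit)) return(hit)
  req <- jsonlite::toJSON(list(
    molecules = data.frame(smiles = smiles, id = ids),
    n_confs = n_confs, seed = seed), auto_unbox = TRUE, digits = NA)
  out <- tryCatch(
    suppressWarnings(system2("python", .rdkit_script(), input = as.character(req),
                             stdout = TRUE, stderr = FALSE)),
    error = function(e) character(0))
  status <- attr(out, "status")
  if ((!is.null(status) && status != 0) || length(out) == 0) {
    abort_co2("RDKit embedding helper failed (is python with rdkit on PATH?)",
              "backend_error")
  }
  res <- jsonlite::fromJSON(paste(out, collapse = ""),
                            simplifyVector = FALSE)$results
  names(res) <- ids
  .rdkit_cache[[key]] <- res
  res
}

## Convert one helper result into a co2_molecule (+ conformer payload).
rdkit_result_to_molecule <- function(r, smiles_input) {
  if (!isTRUE(r$ok)) {
    cls <- if (identical(r$error, "unparseable SMILES")) "smiles_error"
           else "geometry_error"
    abort_co2(sprintf("%s: '%s'", r$error, smiles_input), cls)
  }
  coords <- if (length(r$conformers) > 0) {
    do.call(rbind, lapply(r$conformers[[1]]$coords, unlist))
  } else matrix(0, length(r$elements), 3)  # graph-only request
  bonds <- do.call(rbind, lapply(r$bonds, unlist))
  mol <- new_molecule(
    elements = unlist(r$elements), coords = coords,
    bonds = data.frame(i = bonds[, 1], j = bonds[, 2], order = bonds[, 3]),
    charges = unlist(r$formal_charges), id = r$id,
    smiles = r$canonical_smiles)
  mol$smiles_input <- smiles_input
  mol
}
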