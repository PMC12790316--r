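#' Conformer ensembles
#'
#' Desk-scale conformer generation: seeded ETKDG distance-geometry
#' embedding (RDKit, through the bundled helper) produces candidate
#' geometries which are relaxed and ranked with the UFF force field,
#' filtered to an energy window above the minimum, and deduplicated by
#' heavy-atom RMSD after optimal (Kabsch) superposition. This stands in
#' for metadynamics-based ensemble searches at desk scale; backend
#' (electronic-structure) energies replace the force-field ranking
#' downstream.
#'
#' @name co2screen-conformers
#' @keywords internal
NULL

new_conformer <- function(coordinates, energy, provenance = "embed") {
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  structure(list(coordinates = coordinates, energy = as.numeric(energy),
                 provenance = provenance), class = "co2_conformer")
}

validate_conformer <- function(conf, n_atoms) {
  if (nrow(conf$coordinates) != n_atoms) {
    abort_co2("conformer coordinate count does not match atom count",
              "geometry_error")
  }
  d <- stats::dist(conf$coordinates)
  if (length(d) && min(d) <= 0.5) {
    abort_co2(sprintf("atoms closer than 0.5 Angstrom (min %.3f)", min(d)),
              "geometry_error")
  }
  invisible(conf)
}

#' Optimal-superposition RMSD between two coordinate sets
#'
#' Kabsch alignment (SVD of the cross-covariance after centering), then
#' root-mean-square deviation over the selected atoms.
#'
#' @param a,b Nx3 coordinate matrices over the same atoms.
#' @param subset optional index vector of atoms to align on (e.g. heavy atoms).
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(a, b, subset = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!is.null(subset)) { a <- a[subset, , drop = FALSE]; b <- b[subset, , drop = FALSE] }
  a <- sweep(a, 2, colMeans(a)); b <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(a, b))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((b - a %*% t(rot))^2)))
}

#' Generate a conformer ensemble for a nucleophile record
#'
#' Embeds up to `n_confs` seeded distance-geometry conformers, ranks them
#' by UFF energy (converted to Hartree internally), drops geometries with
#' atom clashes, keeps those within `energy_window` kcal/mol of the
#' minimum, and prunes duplicates with heavy-atom RMSD below
#' `rmsd_threshold`. Conformers are returned sorted ascending by energy.
#' Deterministic: the same record and seed give identical coordinates.
#'
#' @param record a `nucleophile_record`.
#' @param n_confs maximum candidates to embed (default 50).
#' @param seed RNG seed (default 42).
#' @param energy_window retention window above the minimum, kcal/mol
#'   (default 6).
#' @param rmsd_threshold heavy-atom RMSD dedup threshold, Angstrom
#'   (default 0.25).
#' @return a `conformer_ensemble`.
#' @export
embed_ensemble <- function(record, n_confs = 50, seed = 42,
                           energy_window = 6, rmsd_threshold = 0.25) {
  stopifnot(inherits(record, "nucleophile_record"), n_confs >= 1)
  mol <- record$molecule
  confs <- if (!is.null(mol$smiles_input) && !is.na(mol$smiles_input)) {
    res <- rdkit_embed_batch(mol$smiles_input, mol$id, n_confs = n_confs,
                             seed = derive_seed(seed, 7L))[[1]]
    if (!isTRUE(res$ok)) {
      abort_co2(sprintf("embedding failed for %s: %s", record$id, res$error),
                "geometry_error")
    }
    lapply(res$conformers, function(cf)
      new_conformer(do.call(rbind, lapply(cf$coords, unlist)),
                    kcalmol_to_hartree(cf$energy_kcal), "rdkit-etkdg/uff"))
  } else {
    ## graph-built molecule (e.g. after deprotonation): its stored geometry
    ## is the only conformer available
    list(new_conformer(mol$coords, 0, "as-built"))
  }
  confs <- Filter(function(cf) {
    d <- stats::dist(cf$coordinates)
    !(length(d) && min(d) <= 0.7)
  }, confs)
  if (length(confs) == 0) {
    abort_co2(sprintf("all embedding attempts failed for %s", record$id),
              "geometry_error")
  }
  ens <- structure(
    list(record = record, conformers = confs,
         energy_window = energy_window, rmsd_threshold = rmsd_threshold),
    class = "conformer_ensemble")
  prune_ensemble(ens)
}

#' Prune a conformer ensemble by energy window and RMSD
#'
#' Sorts ascending by energy, drops conformers more than `energy_window`
#' kcal/mol above the minimum, then greedily removes any conformer whose
#' heavy-atom RMSD to an already-kept one is below `rmsd_threshold`.
#' Idempotent: pruning a pruned ensemble is a no-op.
#'
#' @param ensemble a `conformer_ensemble`.
#' @return the pruned `conformer_ensemble`.
#' @export
prune_ensemble <- function(ensemble) {
  confs <- ensemble$conformers
  ord <- order(vapply(confs, function(x) x$energy, numeric(1)))
  confs <- confs[ord]
  emin <- confs[[1]]$energy
  win_h <- kcalmol_to_hartree(ensemble$energy_window)
  confs <- Filter(function(x) x$energy - emin <= win_h + 1e-12, confs)
  heavy <- which(ensemble$record$molecule$elements != "H")
  kept <- list()
  for (cf in confs) {
    dup <- any(vapply(kept, function(k)
      kabsch_rmsd(k$coordinates, cf$coordinates, heavy) < ensemble$rmsd_threshold,
      logical(1)))
    if (!dup) kept[[length(kept) + 1]] <- cf
  }
  ensemble$conformers <- kept
  ensemble
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  e <- conformer_energies(x)
  cat(sprintf(
    "<conformer_ensemble %s: %d conformer(s), spread %.2f kcal/mol>\n",
    x$record$id, length(x$conformers),
    if (length(e) > 1) hartree_to_kcalmol(max(e) - min(e)) else 0))
  invisible(x)
}

#' Per-conformer energies of an ensemble (Hartree)
#' @param ensemble a `conformer_ensemble`.
#' @return numeric vector.
#' @export
conformer_energies <- function(ensemble) {
  vapply(ensemble$conformers, function(x) x$energy, numeric(1))
}
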