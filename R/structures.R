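#' Molecular structures and the nucleophilic pattern
#'
#' Candidate nucleophiles are carbanions: a carbon atom CA bearing formal
#' charge -1 whose two neighbors C1 and C2 are both carbons. These three
#' indices anchor the steric descriptors (buried Sterimol B1 measured along
#' CA->C1 and CA->C2) and the electronic site descriptor (Hirshfeld dipole
#' magnitude at CA).
#'
#' @name co2screen-structures
#' @keywords internal
NULL

## Internal molecule container: elements, Nx3 coords (Angstrom), bond table
## (i, j, order), per-atom formal charges. Built from OpenBabel-generated SDF.
new_molecule <- function(elements, coords, bonds, charges, id = "mol",
                         smiles = NA_character_) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  stopifnot(nrow(coords) == length(elements), ncol(coords) == 3)
  structure(
    list(id = id, smiles = smiles, elements = elements, coords = coords,
         bonds = bonds, charges = as.integer(charges)),
    class = "co2_molecule")
}

#' @export
print.co2_molecule <- function(x, ...) {
  cat(sprintf("<co2_molecule %s: %d atoms, %d bonds, charge %+d>\n",
              x$id, length(x$elements), nrow(x$bonds), sum(x$charges)))
  invisible(x)
}

## Map V2000 atom-block charge codes (column 6) to formal charges.
.sdf_charge_code <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                      `5` = -1L, `6` = -2L, `7` = -3L)

## Extract a co2_molecule from one ChemmineR SDF object.
molecule_from_sdf_object <- function(sdf, id = "mol", smiles = NA_character_) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_[0-9]+$", "", rownames(ab))
  coords <- unname(ab[, 1:3, drop = FALSE])
  charges <- .sdf_charge_code[as.character(ab[, "C6"])]
  charges[is.na(charges)] <- 0L
  ## M CHG lines (authoritative when present) are parsed by ChemmineR into
  ## the atom block for ChemmineOB output, so the code column suffices here.
  bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  new_molecule(elements, coords, bonds, charges, id = id, smiles = smiles)
}

#' Build a 3D molecule from a SMILES string
#'
#' Parses the SMILES with RDKit (through the bundled helper), adds explicit
#' hydrogens and generates one seeded distance-geometry conformer. The
#' conversion is deterministic for a given input string and seed.
#'
#' @param smiles a single SMILES string with explicit formal charges.
#' @param id label attached to the molecule.
#' @param seed embedding seed for the base geometry (default 42).
#' @return a `co2_molecule` object (elements, coords, bonds, charges).
#' @export
molecule_from_smiles <- function(smiles, id = "mol", seed = 42) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  res <- rdkit_embed_batch(smiles, id, n_confs = 1, seed = seed)
  rdkit_result_to_molecule(res[[1]], smiles)
}

#' Canonicalize a SMILES string
#' @param smiles a single SMILES string.
#' @return the RDKit canonical SMILES.
#' @export
canonical_smiles <- function(smiles) {
  res <- rdkit_embed_batch(smiles, "canon", n_confs = 0, seed = 0)[[1]]
  if (!isTRUE(res$ok)) {
    abort_co2(sprintf("SMILES could not be canonicalized: '%s'", smiles),
              "smiles_error")
  }
  res$canonical_smiles
}

## Adjacency list from the bond table.
neighbor_list <- function(mol) {
  n <- length(mol$elements)
  nb <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

#' Detect the carbanionic structure pattern
#'
#' Finds the unique carbon with formal charge -1 whose neighbor set contains
#' exactly two carbons, and returns its index together with the indices of
#' those carbon neighbors (ordered ascending).
#'
#' @param mol a `co2_molecule`.
#' @return list with `ca_index`, `c1_index`, `c2_index` (1-based).
#' @details Errors (all classed conditions): `co2screen_pattern_absent` when
#'   no anionic carbon exists, `co2screen_pattern_ambiguous` when more than
#'   one exists (never auto-picked), `co2screen_pattern_mismatch` when the
#'   anionic carbon does not have exactly two carbon neighbors.
#' @export
detect_pattern <- function(mol) {
  anionic <- which(mol$elements == "C" & mol$charges == -1L)
  if (length(anionic) == 0) {
    abort_co2("no carbanionic site (carbon with formal charge -1)",
              "pattern_absent")
  }
  if (length(anionic) > 1) {
    abort_co2(sprintf("ambiguous pattern: %d candidate carbanionic sites",
                      length(anionic)), "pattern_ambiguous")
  }
  ca <- anionic
  nb <- neighbor_list(mol)[[ca]]
  cnb <- sort(nb[mol$elements[nb] == "C"])
  if (length(cnb) != 2) {
    abort_co2(sprintf(
      "carbanionic site has %d carbon neighbor(s); the pattern requires 2",
      length(cnb)), "pattern_mismatch")
  }
  list(ca_index = ca, c1_index = cnb[1], c2_index = cnb[2])
}

#' Construct a nucleophile record from a molecule
#'
#' Validates the carbanion invariants (total charge -1, CA pattern) and
#' packages the molecule with its pattern indices.
#'
#' @param mol a `co2_molecule`.
#' @return a `nucleophile_record`.
#' @export
nucleophile_record <- function(mol) {
  pat <- detect_pattern(mol)
  total_charge <- sum(mol$charges)
  if (total_charge != -1L) {
    abort_co2(sprintf("total charge %+d; carbanion nucleophiles must be -1",
                      total_charge), "charge_error")
  }
  structure(
    list(id = mol$id, smiles = mol$smiles, total_charge = total_charge,
         atoms = data.frame(element = mol$elements,
                            formal_charge = mol$charges),
         ca_index = pat$ca_index, c1_index = pat$c1_index,
         c2_index = pat$c2_index, molecule = mol),
    class = "nucleophile_record")
}

#' @export
print.nucleophile_record <- function(x, ...) {
  cat(sprintf(
    "<nucleophile_record %s: %s, CA=%d C1=%d C2=%d, %d atoms>\n",
    x$id, x$smiles, x$ca_index, x$c1_index, x$c2_index, nrow(x$atoms)))
  invisible(x)
}

#' Parse a SMILES input file into nucleophile records
#'
#' One molecule per line, `SMILES[whitespace]id`; the id is optional
#' (defaults to `mol<line>`). Blank lines and lines starting with `#` are
#' skipped. Every non-skipped line is accounted for: it becomes either a
#' record or a row of the rejects report — invalid input is never silently
#' dropped.
#'
#' @param path path to the SMILES file.
#' @param gen3d generate 3D coordinates while parsing (default TRUE).
#' @return list with `records` (list of `nucleophile_record`) and `rejects`
#'   (data.frame id, line, input, reason).
#' @export
parse_smiles_input <- function(path, gen3d = TRUE) {
  if (!file.exists(path)) {
    abort_co2(sprintf("input file not readable: %s", path), "input_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (length(keep) == 0) {
    abort_co2(sprintf("no input lines in %s", path), "empty_input")
  }
  toks <- lapply(keep, function(ln) strsplit(trimws(lines[ln]), "\\s+")[[1]])
  smi <- vapply(toks, `[`, character(1), 1)
  ids <- vapply(seq_along(toks), function(k)
    if (length(toks[[k]]) >= 2) toks[[k]][2] else sprintf("mol%d", keep[k]),
    character(1))
  batch <- rdkit_embed_batch(smi, ids, n_confs = if (gen3d) 1 else 0,
                             seed = 42)
  records <- list()
  rejects <- data.frame(id = character(), line = integer(),
                        input = character(), reason = character())
  for (k in seq_along(keep)) {
    rec <- tryCatch(
      nucleophile_record(rdkit_result_to_molecule(batch[[k]], smi[k])),
      co2screen_error = function(e) e)
    if (inherits(rec, "nucleophile_record")) {
      records[[ids[k]]] <- rec
    } else {
      rejects <- rbind(rejects, data.frame(
        id = ids[k], line = keep[k], input = smi[k],
        reason = reject_reason(rec)))
    }
  }
  list(records = records, rejects = rejects)
}

## Map a condition to the reject-reason taxonomy used in reports.
reject_reason <- function(cond) {
  cls <- class(cond)
  if (any(grepl("pattern_absent", cls))) return("no carbanionic site")
  if (any(grepl("pattern_mismatch", cls))) return("pattern mismatch")
  if (any(grepl("pattern_ambiguous", cls))) return("ambiguous pattern")
  if (any(grepl("charge_error", cls))) return("not a monoanion")
  if (any(grepl("smiles_error", cls))) return("unparseable SMILES")
  if (any(grepl("geometry_error", cls))) return("embedding failure")
  if (any(grepl("convergence", cls))) return("backend non-convergence")
  if (any(grepl("parse_error", cls))) return("engine output parse failure")
  if (any(grepl("feature_error", cls))) return("missing feature")
  paste("error:", conditionMessage(cond))
}

#' Deprotonate a molecule at a given atom
#'
#' Helper for users starting from the neutral C-H acid: removes one hydrogen
#' bonded to `atom_index` and assigns formal charge -1 to that atom.
#'
#' @param mol a `co2_molecule`.
#' @param atom_index 1-based index of the atom to deprotonate.
#' @return a new `co2_molecule` with one H fewer and charge lowered by one.
#' @export
deprotonate <- function(mol, atom_index) {
  nb <- neighbor_list(mol)[[atom_index]]
  hs <- nb[mol$elements[nb] == "H"]
  if (length(hs) == 0) {
    abort_co2(sprintf("atom %d has no hydrogen to remove", atom_index),
              "deprotonation_error")
  }
  drop <- hs[1]
  keep <- setdiff(seq_along(mol$elements), drop)
  remap <- integer(length(mol$elements)); remap[keep] <- seq_along(keep)
  bonds <- mol$bonds[mol$bonds$i != drop & mol$bonds$j != drop, ]
  bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
  charges <- mol$charges[keep]
  charges[remap[atom_index]] <- charges[remap[atom_index]] - 1L
  new_molecule(mol$elements[keep], mol$coords[keep, , drop = FALSE],
               bonds, charges, id = mol$id, smiles = NA_character_)
}
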