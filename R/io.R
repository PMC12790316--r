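#' Structure file input/output
#'
#' Multi-frame XYZ (count line, comment line, `element x y z` records,
#' Angstrom) and SDF v2000. XYZ round-trips losslessly at six decimal
#' places; ensemble energies are carried on the comment line as
#' `energy=<Hartree>`.
#'
#' @name co2screen-io
#' @keywords internal
NULL

#' Read a (multi-frame) XYZ file
#'
#' @param path path to the XYZ file.
#' @return list of frames, each `list(elements, coords, comment, energy)`
#'   (`energy` is NA unless the comment carries `energy=<value>`).
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) {
    abort_co2(sprintf("XYZ file not readable: %s", path), "input_error")
  }
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  ln <- 1
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln]))) { ln <- ln + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(n) || n < 1) {
      abort_co2(sprintf("line %d: malformed atom count '%s'", ln, lines[ln]),
                "format_error")
    }
    if (ln + 1 + n > length(lines)) {
      abort_co2(sprintf(
        "line %d: frame declares %d atoms but file ends early", ln, n),
        "format_error")
    }
    comment <- lines[ln + 1]
    elements <- character(n)
    coords <- matrix(NA_real_, n, 3)
    for (k in seq_len(n)) {
      row <- ln + 1 + k
      toks <- strsplit(trimws(lines[row]), "\\s+")[[1]]
      if (length(toks) < 4) {
        abort_co2(sprintf("line %d: expected 'element x y z'", row),
                  "format_error")
      }
      if (!grepl("^[A-Z][a-z]?$", toks[1])) {
        abort_co2(sprintf("line %d: bad element symbol '%s'", row, toks[1]),
                  "format_error")
      }
      xyz <- suppressWarnings(as.numeric(toks[2:4]))
      if (anyNA(xyz)) {
        abort_co2(sprintf("line %d: non-numeric coordinate", row),
                  "format_error")
      }
      elements[k] <- toks[1]
      coords[k, ] <- xyz
    }
    energy <- NA_real_
    m <- regmatches(comment, regexec("energy=([-+0-9.eE]+)", comment))[[1]]
    if (length(m) == 2) energy <- as.numeric(m[2])
    frames[[length(frames) + 1]] <-
      list(elements = elements, coords = coords, comment = comment,
           energy = energy)
    ln <- ln + 2 + n
  }
  if (length(frames) == 0) {
    abort_co2(sprintf("no frames in XYZ file %s", path), "format_error")
  }
  frames
}

#' Write structures to a (multi-frame) XYZ file
#'
#' @param x a `conformer_ensemble`, a single `co2_conformer` plus
#'   `elements`, or a list of frames as returned by [read_xyz()].
#' @param path output path.
#' @param elements element symbols (required unless `x` carries them).
#' @return the path, invisibly.
#' @export
write_xyz <- function(x, path, elements = NULL) {
  frames <- if (inherits(x, "conformer_ensemble")) {
    els <- x$record$molecule$elements
    lapply(x$conformers, function(cf)
      list(elements = els, coords = cf$coordinates,
           comment = sprintf("%s energy=%.10f", x$record$id, cf$energy)))
  } else if (inherits(x, "co2_conformer")) {
    stopifnot(!is.null(elements))
    list(list(elements = elements, coords = x$coordinates,
              comment = sprintf("energy=%.10f", x$energy)))
  } else x
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    writeLines(as.character(nrow(fr$coords)), con)
    writeLines(if (is.null(fr$comment)) "" else fr$comment, con)
    writeLines(sprintf("%-3s %14.6f %14.6f %14.6f", fr$elements,
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]), con)
  }
  invisible(path)
}

#' Read an SDF (v2000) file into molecules
#'
#' Thin wrapper over ChemmineR's SDF reader returning the package's
#' molecule container.
#'
#' @param path path to the SDF file.
#' @return list of `co2_molecule` objects.
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) {
    abort_co2(sprintf("SDF file not readable: %s", path), "input_error")
  }
  set <- tryCatch(ChemmineR::read.SDFset(path),
                  error = function(e)
                    abort_co2(sprintf("SDF parse failure: %s",
                                      conditionMessage(e)), "format_error"))
  ids <- ChemmineR::sdfid(set)
  lapply(seq_along(set), function(k)
    molecule_from_sdf_object(set[[k]],
                             id = if (nzchar(ids[k])) ids[k]
                                  else sprintf("mol%d", k)))
}

#' Read an ensemble back from a multi-frame XYZ file
#'
#' @param path XYZ path written by [write_xyz()].
#' @param record the `nucleophile_record` the frames belong to.
#' @return a `conformer_ensemble` (unpruned).
#' @export
read_xyz_ensemble <- function(path, record, energy_window = 6,
                              rmsd_threshold = 0.25) {
  frames <- read_xyz(path)
  confs <- lapply(frames, function(fr) {
    if (length(fr$elements) != nrow(record$atoms)) {
      abort_co2("frame atom count does not match record", "format_error")
    }
    new_conformer(fr$coords,
                  if (is.na(fr$energy)) 0 else fr$energy, "xyz-file")
  })
  structure(list(record = record, conformers = confs,
                 energy_window = energy_window,
                 rmsd_threshold = rmsd_threshold),
            class = "conformer_ensemble")
}
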