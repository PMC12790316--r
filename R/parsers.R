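#' Engine output parsing
#'
#' Engine output formats are registered by name in a dialect registry;
#' [parse_engine_output()] dispatches on the dialect and returns a fully
#' populated [qm_result()] with units normalized to Hartree / Angstrom /
#' atomic units, or raises a typed parse error naming the missing section —
#' never a partially populated silent result.
#'
#' Built-in dialects:
#' \describe{
#'   \item{qcout}{sectioned plain text: `[geometry]`, `[scf]`, `[orbitals]`
#'     (index, occupancy, energy; HOMO = highest orbital with occupancy
#'     > 0), `[thermo]`, `[hirshfeld]` (element, charge, dipole x y z),
#'     terminated by `[end]`.}
#'   \item{proptable}{flat `key value` pairs with whitespace-separated
#'     vectors, for structured property files.}
#' }
#'
#' @name co2screen-parsers
#' @keywords internal
NULL

.dialects <- new.env(parent = emptyenv())

#' Register an engine-output dialect
#'
#' @param name dialect name.
#' @param parser function(lines) -> `qm_result`.
#' @export
register_dialect <- function(name, parser) {
  stopifnot(is.character(name), is.function(parser))
  assign(name, parser, envir = .dialects)
  invisible(name)
}

#' List registered engine-output dialects
#' @return character vector of dialect names.
#' @export
list_dialects <- function() ls(.dialects)

#' Parse an engine output file into a QM result
#'
#' @param path path to the output file.
#' @param dialect registered dialect name.
#' @return a `qm_result`.
#' @export
parse_engine_output <- function(path, dialect = "qcout") {
  if (!file.exists(path)) {
    abort_co2(sprintf("engine output not readable: %s", path), "input_error")
  }
  parser <- .dialects[[dialect]]
  if (is.null(parser)) {
    abort_co2(sprintf("unknown engine-output dialect '%s' (known: %s)",
                      dialect, paste(list_dialects(), collapse = ", ")),
              "dialect_error")
  }
  parser(readLines(path, warn = FALSE))
}

## --- qcout dialect -------------------------------------------------------

parse_qcout <- function(lines) {
  section_at <- function(tag) which(trimws(lines) == paste0("[", tag, "]"))
  grab <- function(tag, required = TRUE) {
    at <- section_at(tag)
    if (length(at) != 1) {
      if (required) {
        abort_co2(sprintf("truncated or malformed output: section [%s] %s",
                          tag, if (length(at)) "duplicated" else "missing"),
                  "parse_error")
      }
      return(NULL)
    }
    ends <- grep("^\\[", trimws(lines))
    stop_at <- ends[ends > at]
    if (length(stop_at) == 0) {
      abort_co2(sprintf("output truncated inside section [%s]", tag),
                "parse_error")
    }
    body <- lines[(at + 1):(min(stop_at) - 1)]
    body[nzchar(trimws(body)) & !grepl("^\\s*#", body)]
  }
  if (length(section_at("end")) != 1) {
    abort_co2("output truncated: terminator [end] missing", "parse_error")
  }
  geom <- grab("geometry")
  gtoks <- strsplit(trimws(geom), "\\s+")
  if (any(lengths(gtoks) < 4)) {
    abort_co2("malformed [geometry] record", "parse_error")
  }
  elements <- vapply(gtoks, `[`, character(1), 1)
  coords <- t(vapply(gtoks, function(t) as.numeric(t[2:4]), numeric(3)))
  kv <- function(body, key) {
    row <- grep(paste0("^\\s*", key, "\\b"), body, value = TRUE)
    if (length(row) == 0) {
      abort_co2(sprintf("missing property '%s'", key), "parse_error")
    }
    as.numeric(strsplit(trimws(row[1]), "\\s+")[[1]][-1])
  }
  scf <- kv(grab("scf"), "energy_hartree")
  orb_body <- grab("orbitals")
  otoks <- strsplit(trimws(orb_body), "\\s+")
  occ <- vapply(otoks, function(t) as.numeric(t[2]), numeric(1))
  oen <- vapply(otoks, function(t) as.numeric(t[3]), numeric(1))
  if (anyNA(occ) || anyNA(oen)) {
    abort_co2("malformed [orbitals] record", "parse_error")
  }
  if (!any(occ > 0)) {
    abort_co2("no occupied orbital in [orbitals]", "parse_error")
  }
  homo_index <- max(which(occ > 0))
  thermo <- grab("thermo", required = FALSE)
  gibbs <- if (is.null(thermo)) {
    abort_co2("no [thermo] section: Gibbs free energy unavailable",
              "missing_property")
  } else kv(thermo, "gibbs_hartree")
  hb <- grab("hirshfeld")
  htoks <- strsplit(trimws(hb), "\\s+")
  if (length(htoks) != length(elements) || any(lengths(htoks) < 5)) {
    abort_co2("[hirshfeld] rows do not match atom count", "parse_error")
  }
  charges <- vapply(htoks, function(t) as.numeric(t[2]), numeric(1))
  dip <- t(vapply(htoks, function(t) as.numeric(t[3:5]), numeric(3)))
  qm_result(optimized_coordinates = coords, electronic_energy = scf,
            gibbs_free_energy = gibbs, orbital_energies = oen,
            homo_index = homo_index, hirshfeld_charges = charges,
            hirshfeld_atomic_dipoles = dip)
}

## --- proptable dialect (flat key/value property files) -------------------

parse_proptable <- function(lines) {
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- list()
  for (l in lines) {
    toks <- strsplit(trimws(l), "\\s+")[[1]]
    kv[[toks[1]]] <- toks[-1]
  }
  need <- function(key, numeric = TRUE) {
    v <- kv[[key]]
    if (is.null(v)) {
      abort_co2(sprintf("property file missing key '%s'", key),
                "parse_error")
    }
    if (numeric) as.numeric(v) else v
  }
  elements <- need("elements", numeric = FALSE)
  n <- length(elements)
  coords <- matrix(need("coordinates"), ncol = 3, byrow = TRUE)
  if (nrow(coords) != n) {
    abort_co2("coordinates do not match element count", "parse_error")
  }
  orb <- need("orbital_energies")
  qm_result(
    optimized_coordinates = coords,
    electronic_energy = need("electronic_energy"),
    gibbs_free_energy = need("gibbs_free_energy"),
    orbital_energies = orb,
    homo_index = as.integer(need("homo_index")),
    hirshfeld_charges = need("hirshfeld_charges"),
    hirshfeld_atomic_dipoles = matrix(need("hirshfeld_atomic_dipoles"),
                                      ncol = 3, byrow = TRUE))
}

## dialect registration at load time
.onLoad <- function(libname, pkgname) {
  register_dialect("qcout", parse_qcout)
  register_dialect("proptable", parse_proptable)
}
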