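#' Electronic-structure backend contract
#'
#' The pipeline consumes per-conformer electronic-structure properties
#' (optimized geometry, SCF and Gibbs free energies, orbital energies with
#' the HOMO identified, Hirshfeld charges and atomic dipoles) through a
#' backend contract. Two settings presets mirror the two-round protocol:
#' a cheap screening level for geometries and the HOMO filter, and a
#' refined affinity level for the reaction free energies. Backends are
#' engine-agnostic; the method strings are passed through, never
#' interpreted.
#'
#' @name co2screen-qm
#' @keywords internal
NULL

#' Electronic-structure settings
#'
#' @param method level-of-theory string (passed through to backends).
#' @param solvent_model implicit solvation model name.
#' @param solvent solvent name.
#' @param temperature thermochemistry temperature in Kelvin (> 0).
#' @param charge total molecular charge.
#' @param multiplicity spin multiplicity (>= 1).
#' @return a `qm_settings` object.
#' @export
qm_settings <- function(method = "PBE-D3(BJ)/def2-TZVPD",
                        solvent_model = "SMD", solvent = "DMSO",
                        temperature = 298.15, charge = -1L,
                        multiplicity = 1L) {
  stopifnot(temperature > 0, multiplicity >= 1)
  structure(list(method = method, solvent_model = solvent_model,
                 solvent = solvent, temperature = temperature,
                 charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity)),
            class = "qm_settings")
}

#' Settings presets for the two-round protocol
#'
#' `"screening"`: geometry + screening properties at the cheap level.
#' `"affinity"`: free energies at the refined level. `"affinity_20C"` is the
#' affinity preset at 293.15 K (adduct stability quoted at 20 C in DMSO).
#'
#' @param name preset name.
#' @param ... overrides passed to [qm_settings()].
#' @return a `qm_settings` object.
#' @export
qm_preset <- function(name = c("screening", "affinity", "affinity_20C"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    screening = list(method = "PBE-D3(BJ)/def2-TZVPD"),
    affinity = list(method = "B3LYP-D3(BJ)/def2-TZVPD"),
    affinity_20C = list(method = "B3LYP-D3(BJ)/def2-TZVPD",
                        temperature = 293.15))
  do.call(qm_settings, utils::modifyList(base, list(...)))
}

settings_hash <- function(settings) rlang::hash(unclass(settings))

#' Construct and validate a QM result
#'
#' @param optimized_coordinates Nx3 matrix, Angstrom.
#' @param electronic_energy SCF energy, Hartree.
#' @param gibbs_free_energy Gibbs free energy, Hartree.
#' @param orbital_energies ordered numeric vector, Hartree.
#' @param homo_index 1-based index of the HOMO in `orbital_energies`.
#' @param hirshfeld_charges per-atom charges, e.
#' @param hirshfeld_atomic_dipoles Nx3 matrix of atomic dipoles, atomic units.
#' @param settings_hash provenance hash of the settings used.
#' @return a validated `qm_result`.
#' @export
qm_result <- function(optimized_coordinates, electronic_energy,
                      gibbs_free_energy, orbital_energies, homo_index,
                      hirshfeld_charges, hirshfeld_atomic_dipoles,
                      settings_hash = NA_character_) {
  res <- structure(
    list(optimized_coordinates = as.matrix(optimized_coordinates),
         electronic_energy = electronic_energy,
         gibbs_free_energy = gibbs_free_energy,
         orbital_energies = orbital_energies,
         homo_index = as.integer(homo_index),
         homo_energy = orbital_energies[homo_index],
         hirshfeld_charges = hirshfeld_charges,
         hirshfeld_atomic_dipoles = as.matrix(hirshfeld_atomic_dipoles),
         settings_hash = settings_hash),
    class = "qm_result")
  validate_qm_result(res)
}

validate_qm_result <- function(res) {
  n <- nrow(res$optimized_coordinates)
  if (length(res$hirshfeld_charges) != n ||
      nrow(res$hirshfeld_atomic_dipoles) != n) {
    abort_co2("per-atom property length does not match atom count",
              "result_error")
  }
  if (res$homo_index < 1 || res$homo_index > length(res$orbital_energies)) {
    abort_co2("HOMO index outside the orbital energy list", "result_error")
  }
  if (!isTRUE(all.equal(res$homo_energy,
                        res$orbital_energies[res$homo_index]))) {
    abort_co2("homo_energy inconsistent with orbital_energies[homo_index]",
              "result_error")
  }
  if (res$homo_index < length(res$orbital_energies) &&
      res$orbital_energies[res$homo_index + 1] <= res$homo_energy) {
    abort_co2("HOMO energy not below LUMO energy", "result_error")
  }
  invisible(res)
}

#' Hirshfeld site-dipole magnitude at an atom
#'
#' The scalar electronic site descriptor: Euclidean norm of the Hirshfeld
#' atomic dipole vector at the given atom (atomic units) — the only
#' rotation-invariant scalar of the vector.
#'
#' @param result a `qm_result`.
#' @param atom_index 1-based atom index (typically CA).
#' @return dipole magnitude in atomic units.
#' @export
site_dipole <- function(result, atom_index) {
  sqrt(sum(result$hirshfeld_atomic_dipoles[atom_index, ]^2))
}

ALL_CAPABILITIES <- c("optimize", "single_point", "thermochemistry",
                      "hirshfeld")

#' Construct a backend object
#'
#' A backend declares capabilities and supplies a `run` function
#' `(elements, coords, settings, label)` returning a `qm_result`. A
#' declared capability must populate the corresponding result fields.
#'
#' @param name backend name.
#' @param capabilities subset of
#'   `c("optimize","single_point","thermochemistry","hirshfeld")`.
#' @param run the run function.
#' @return a `qm_backend` with a per-backend call counter and result cache.
#' @export
qm_backend <- function(name, capabilities, run) {
  stopifnot(all(capabilities %in% ALL_CAPABILITIES), is.function(run))
  state <- new.env(parent = emptyenv())
  state$calls <- 0L
  state$cache <- new.env(parent = emptyenv())
  structure(list(name = name, capabilities = capabilities, run = run,
                 state = state),
            class = "qm_backend")
}

#' Number of engine invocations a backend has performed
#'
#' Cache hits do not increment the counter; used to verify the two-round
#' economy of the screening pipeline.
#'
#' @param backend a `qm_backend`.
#' @return integer call count.
#' @export
backend_calls <- function(backend) backend$state$calls

#' Reset a backend's call counter (the cache is kept)
#' @param backend a `qm_backend`.
#' @export
reset_backend_calls <- function(backend) {
  backend$state$calls <- 0L
  invisible(backend)
}

#' Run a backend on one conformer, with content-addressed caching
#'
#' Results are cached in-memory keyed by the hash of (elements, coordinates
#' rounded to 1e-8 Angstrom, settings, backend name); identical reruns never
#' invoke the engine. With `cache_dir` set, results are additionally
#' persisted on disk under the same key.
#'
#' @param elements element symbols.
#' @param coords Nx3 coordinates, Angstrom.
#' @param settings a `qm_settings`.
#' @param backend a `qm_backend`.
#' @param label optional structure label passed to file-based backends.
#' @param require capabilities needed by the caller (default: all declared
#'   uses); missing capabilities raise a capability error before any compute.
#' @param cache_dir optional directory for a persistent result cache.
#' @return a `qm_result`.
#' @export
run_backend <- function(elements, coords, settings, backend, label = NULL,
                        require = c("optimize", "single_point",
                                    "thermochemistry", "hirshfeld"),
                        cache_dir = NULL) {
  stopifnot(inherits(backend, "qm_backend"), inherits(settings, "qm_settings"))
  missing_caps <- setdiff(require, backend$capabilities)
  if (length(missing_caps)) {
    abort_co2(sprintf("backend '%s' lacks capability: %s", backend$name,
                      paste(missing_caps, collapse = ", ")),
              "capability_error")
  }
  key <- rlang::hash(list(elements, round(as.matrix(coords), 8),
                          unclass(settings), backend$name, label))
  if (!is.null(backend$state$cache[[key]])) return(backend$state$cache[[key]])
  if (!is.null(cache_dir)) {
    f <- file.path(cache_dir, paste0(key, ".rds"))
    if (file.exists(f)) {
      res <- readRDS(f)
      backend$state$cache[[key]] <- res
      return(res)
    }
  }
  backend$state$calls <- backend$state$calls + 1L
  res <- backend$run(elements, coords, settings, label)
  res$settings_hash <- settings_hash(settings)
  validate_qm_result(res)
  backend$state$cache[[key]] <- res
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(res, file.path(cache_dir, paste0(key, ".rds")))
  }
  res
}

#' Deterministic mock electronic-structure backend
#'
#' Computes smooth, rotation- and translation-invariant pseudo-properties
#' from composition and interatomic distances alone. The numbers are
#' NON-PHYSICAL: the mock exists so the pipeline, caching, filtering and
#' descriptor plumbing can be exercised without a quantum-chemistry engine.
#' Identical inputs give bit-identical results.
#'
#' @return a `qm_backend` with all capabilities.
#' @export
mock_backend <- function() {
  qm_backend("mock", ALL_CAPABILITIES, function(elements, coords, settings,
                                                label) {
    coords <- as.matrix(coords)
    n <- nrow(coords)
    z <- atomic_numbers(elements)
    dm <- as.matrix(stats::dist(coords))
    ## rotation-invariant geometry summaries
    pair <- if (n > 1) dm[upper.tri(dm)] else numeric(0)
    s1 <- if (length(pair)) mean(exp(-pair)) else 0
    s2 <- if (length(pair)) mean(1 / pair) else 0
    e_el <- -0.1 * sum(z^2) - 0.01 * sum(exp(-pair / 2))
    n_elec <- sum(z) - settings$charge
    n_occ <- max(1L, n_elec %/% 2L)
    ## smooth HOMO energy centered near the chemically relevant range, with
    ## enough spread that typical small-carbanion inputs fall on both sides
    ## of the -0.140 Hartree screening threshold
    e_homo <- -0.1375 + 0.025 * tanh(8 * (s1 - 0.075)) +
      0.005 * tanh(s2 - 1)
    gap <- 0.08 + 0.02 * tanh(s2)
    orb <- c(e_homo - 0.03 * ((n_occ - 1):1), e_homo, e_homo + gap,
             e_homo + 2 * gap)
    orb <- orb[seq_len(n_occ + 2)]
    gibbs <- e_el + 0.03 * sqrt(n) - settings$temperature * 1e-5 * n
    ## electronegativity-driven smooth charges, renormalized to the total
    en <- .ELECTRONEG[elements]
    en[is.na(en)] <- 2.2
    q0 <- -0.1 * (en - mean(en))
    q <- q0 + (settings$charge - sum(q0)) / n
    ## neighbor-asymmetry dipole vectors (equivariant; magnitudes invariant)
    dip <- matrix(0, n, 3)
    if (n > 1) {
      for (i in seq_len(n)) {
        for (j in seq_len(n)[-i]) {
          v <- coords[j, ] - coords[i, ]
          d <- sqrt(sum(v^2))
          dip[i, ] <- dip[i, ] + 0.2 * (en[j] - en[i] + 0.5) * v / d * exp(-d)
        }
      }
    }
    qm_result(optimized_coordinates = coords, electronic_energy = e_el,
              gibbs_free_energy = gibbs, orbital_energies = orb,
              homo_index = n_occ, hirshfeld_charges = q,
              hirshfeld_atomic_dipoles = dip)
  })
}

#' Backend reading precomputed engine output files from a directory
#'
#' Looks up `<label>.<ext>` in `dir` and parses it with
#' [parse_engine_output()]. This is the backend-free input path for users
#' who ran their engine elsewhere.
#'
#' @param dir directory of engine output files.
#' @param dialect output dialect name (see [register_dialect()]).
#' @param ext file extension (default `"out"`).
#' @return a `qm_backend`.
#' @export
file_backend <- function(dir, dialect = "qcout", ext = "out") {
  qm_backend(paste0("file:", dir), ALL_CAPABILITIES,
             function(elements, coords, settings, label) {
    if (is.null(label)) {
      abort_co2("file backend requires a structure label", "input_error")
    }
    path <- file.path(dir, paste0(label, ".", ext))
    if (!file.exists(path)) {
      abort_co2(sprintf("no engine output for '%s' (%s)", label, path),
                "missing_property")
    }
    parse_engine_output(path, dialect = dialect)
  })
}
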