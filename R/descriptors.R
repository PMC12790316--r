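#' Steric and electronic molecular descriptors
#'
#' Verloop Sterimol parameters are computed from van der Waals spheres
#' projected about the attach->axis vector: L is the maximal extent along
#' the axis, and for each direction d perpendicular to the axis the width
#' is `max_i(<d, x_i - x_attach> + r_i)`; B1 and B5 are the minimal and
#' maximal widths over all perpendicular directions. The attach atom itself
#' is excluded from the projections (it is the attachment point); all other
#' atoms contribute. The buried variant first discards atoms whose center
#' lies beyond a cutoff sphere around the attach atom, capturing only local
#' steric bulk.
#'
#' @name co2screen-descriptors
#' @keywords internal
NULL

#' Boltzmann weights of a conformer ensemble
#'
#' `w_i = exp(-(E_i - E_min)/kT) / sum_j exp(-(E_j - E_min)/kT)`; the shift
#' by the minimum energy is applied for numerical stability. Weights sum to
#' one to within 1e-12.
#'
#' @param energies conformer energies in Hartree.
#' @param temperature temperature in Kelvin (> 0).
#' @return numeric vector of weights summing to 1.
#' @export
boltzmann_weights <- function(energies, temperature = 298.15) {
  if (length(energies) == 0) {
    abort_co2("empty energy list", "input_error")
  }
  stopifnot(temperature > 0)
  x <- exp(-(energies - min(energies)) / (KB_HARTREE * temperature))
  x / sum(x)
}

#' Ensemble aggregation of a per-conformer descriptor
#'
#' Collects the four ensemble statistics used throughout: minimum, maximum,
#' Boltzmann-weighted average, and the value of the lowest-energy conformer
#' (ties resolved to the lowest index).
#'
#' @param values per-conformer descriptor values.
#' @param energies per-conformer energies, Hartree (same length).
#' @param temperature Kelvin.
#' @param name,units descriptor metadata.
#' @return an `ensemble_descriptor`: list(min, max, boltz, lowE, name, units).
#' @export
aggregate_ensemble <- function(values, energies, temperature = 298.15,
                               name = "descriptor", units = "") {
  if (length(values) != length(energies)) {
    abort_co2("values and energies differ in length", "input_error")
  }
  w <- boltzmann_weights(energies, temperature)
  structure(list(name = name,
                 min = min(values), max = max(values),
                 boltz = sum(w * values),
                 lowE = values[which.min(energies)],
                 units = units),
            class = "ensemble_descriptor")
}

## width of the vdW silhouette along in-plane angle theta:
## max_i(A_i * cos(theta - phi_i) + r_i)
.width_fun <- function(amp, phase, radii) {
  function(theta) max(amp * cos(theta - phase) + radii)
}

## golden-section minimizer on [lo, hi] (unimodal bracket), tol in radians
golden_min <- function(f, lo, hi, tol = 1e-12) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c <- b - gr * (b - a); d <- a + gr * (b - a)
  fc <- f(c); fd <- f(d)
  while (b - a > tol) {
    if (fc < fd) { b <- d; d <- c; fd <- fc; c <- b - gr * (b - a); fc <- f(c) }
    else { a <- c; c <- d; fc <- fd; d <- a + gr * (b - a); fd <- f(d) }
  }
  x <- (a + b) / 2
  list(x = x, f = f(x))
}

#' Sterimol parameters L, B1, B5
#'
#' Direction search for B1/B5: widths are evaluated on a coarse angular
#' grid; every local extremum is then refined by golden-section search to
#' machine-level tolerance, which makes the result invariant under rigid
#' motions of the input geometry.
#'
#' @param coords Nx3 coordinates, Angstrom.
#' @param radii per-atom van der Waals radii, Angstrom.
#' @param attach_index 1-based index of the attachment atom (excluded from
#'   the projections; origin of the axis).
#' @param axis_index 1-based index of the atom defining the axis direction.
#' @param angular_step coarse grid spacing in degrees (default 1).
#' @return a `sterimol_values` list: L, B1, B5 (Angstrom), axis indices.
#' @export
sterimol <- function(coords, radii, attach_index, axis_index,
                     angular_step = 1) {
  coords <- as.matrix(coords)
  stopifnot(length(radii) == nrow(coords), attach_index != axis_index)
  origin <- coords[attach_index, ]
  u <- coords[axis_index, ] - origin
  nu <- sqrt(sum(u^2))
  if (nu < 1e-6) {
    abort_co2("attach and axis atoms are coincident", "geometry_error")
  }
  u <- u / nu
  idx <- setdiff(seq_len(nrow(coords)), attach_index)
  v <- sweep(coords[idx, , drop = FALSE], 2, origin)
  r <- radii[idx]
  L <- max(v %*% u + r)
  ## orthonormal in-plane basis (choice of phase does not affect extrema)
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  a <- drop(v %*% e1); b <- drop(v %*% e2)
  amp <- sqrt(a^2 + b^2)
  phase <- atan2(b, a)
  wf <- .width_fun(amp, phase, r)
  step <- angular_step * pi / 180
  grid <- seq(0, 2 * pi, by = step)
  wg <- vapply(grid, wf, numeric(1))
  m <- length(grid) - 1  # grid[m+1] == 2*pi aliases grid[1]
  wg <- wg[seq_len(m)]
  prev <- c(m, seq_len(m - 1)); nxt <- c(2:m, 1)
  refine <- function(at, maximize) {
    f <- if (maximize) function(t) -wf(t) else wf
    res <- golden_min(f, grid[at] - step, grid[at] + step)
    if (maximize) -res$f else res$f
  }
  lmin <- which(wg <= wg[prev] & wg <= wg[nxt])
  lmax <- which(wg >= wg[prev] & wg >= wg[nxt])
  B1 <- min(vapply(lmin, refine, numeric(1), maximize = FALSE))
  B5 <- max(vapply(lmax, refine, numeric(1), maximize = TRUE))
  structure(list(L = L, B1 = B1, B5 = B5,
                 axis = c(attach = attach_index, axis = axis_index),
                 buried_radius = NA_real_),
            class = "sterimol_values")
}

#' @export
print.sterimol_values <- function(x, ...) {
  cat(sprintf("<sterimol L=%.3f B1=%.3f B5=%.3f%s>\n", x$L, x$B1, x$B5,
              if (is.na(x$buried_radius)) ""
              else sprintf(" buried@%.1fA", x$buried_radius)))
  invisible(x)
}

#' Brute-force Sterimol reference scan
#'
#' Independent reference implementation: evaluates the perpendicular width
#' directly on a dense full-circle grid (default 0.01 degrees) with no
#' refinement, taking B1/B5 as the plain minimum/maximum. Used as the
#' oracle for the grid+refinement search and by the fixture generators.
#'
#' @inheritParams sterimol
#' @param scan_step dense grid spacing in degrees (default 0.01).
#' @return a `sterimol_values` list.
#' @export
sterimol_scan <- function(coords, radii, attach_index, axis_index,
                          scan_step = 0.01) {
  coords <- as.matrix(coords)
  origin <- coords[attach_index, ]
  u <- coords[axis_index, ] - origin
  u <- u / sqrt(sum(u^2))
  idx <- setdiff(seq_len(nrow(coords)), attach_index)
  v <- sweep(coords[idx, , drop = FALSE], 2, origin)
  r <- radii[idx]
  L <- max(v %*% u + r)
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  theta <- seq(0, 2 * pi, by = scan_step * pi / 180)
  ## widths over the dense grid, vectorized over atoms x angles
  ct <- cos(theta); st <- sin(theta)
  W <- apply(outer(drop(v %*% e1), ct) + outer(drop(v %*% e2), st) + r,
             2, max)
  structure(list(L = L, B1 = min(W), B5 = max(W),
                 axis = c(attach = attach_index, axis = axis_index),
                 buried_radius = NA_real_),
            class = "sterimol_values")
}

## atoms retained inside the buried sphere: the attach atom and the axis
## atom are always kept (the axis must stay defined); others strictly by
## center distance from the attach atom.
buried_atom_set <- function(coords, attach_index, axis_index, buried_radius) {
  d <- sqrt(rowSums(sweep(as.matrix(coords), 2,
                          as.matrix(coords)[attach_index, ])^2))
  keep <- which(d <= buried_radius | seq_along(d) %in%
                  c(attach_index, axis_index))
  if (sum(keep != attach_index) == 0 ||
      all(d[setdiff(seq_along(d), attach_index)] > buried_radius)) {
    abort_co2("all substituent atoms lie outside the buried sphere",
              "degenerate_geometry")
  }
  keep
}

#' Buried Sterimol parameters
#'
#' Identical to [sterimol()] after excluding atoms whose center lies
#' farther than `buried_radius` from the attach atom (excluded atoms
#' contribute nothing); equals the plain Sterimol when the sphere contains
#' every atom.
#'
#' @inheritParams sterimol
#' @param buried_radius cutoff sphere radius, Angstrom (> 0).
#' @return a `sterimol_values` list with `buried_radius` recorded.
#' @export
buried_sterimol <- function(coords, radii, attach_index, axis_index,
                            buried_radius = 5.5, angular_step = 1) {
  stopifnot(buried_radius > 0)
  keep <- buried_atom_set(coords, attach_index, axis_index, buried_radius)
  res <- sterimol(as.matrix(coords)[keep, , drop = FALSE], radii[keep],
                  match(attach_index, keep), match(axis_index, keep),
                  angular_step = angular_step)
  res$axis <- c(attach = attach_index, axis = axis_index)
  res$buried_radius <- buried_radius
  res
}

#' Buried Sterimol B1 at the carbanionic site
#'
#' Computes the buried Sterimol with attach = CA twice — once along CA->C1
#' and once along CA->C2 — and returns the arithmetic mean of the two B1
#' values; both per-axis values are retained.
#'
#' @param coords Nx3 coordinates of one conformer, Angstrom.
#' @param record the `nucleophile_record` providing CA/C1/C2 indices.
#' @param buried_radius cutoff sphere radius, Angstrom.
#' @param radii_table optional named radius overrides (see [vdw_radii()]).
#' @param angular_step coarse grid spacing in degrees.
#' @return list with `b1` (mean), `per_axis` (named c1/c2 values).
#' @export
site_b1 <- function(coords, record, buried_radius = 5.5, radii_table = NULL,
                    angular_step = 1) {
  radii <- vdw_radii(record$atoms$element, radii_table)
  v1 <- buried_sterimol(coords, radii, record$ca_index, record$c1_index,
                        buried_radius, angular_step)$B1
  v2 <- buried_sterimol(coords, radii, record$ca_index, record$c2_index,
                        buried_radius, angular_step)$B1
  list(b1 = (v1 + v2) / 2, per_axis = c(c1 = v1, c2 = v2))
}

#' CO2 affinity from Gibbs free energies
#'
#' `CO2A = -(G_adduct - G_nucleophile - G_CO2) * 627.509474` kcal/mol:
#' the negative Gibbs free reaction energy of CO2 addition. Positive values
#' indicate a thermodynamically stable carboxylate adduct.
#'
#' @param g_adduct,g_nucleophile,g_co2 Gibbs free energies in Hartree, all
#'   from the same settings preset.
#' @param settings_hashes optional character vector of the three settings
#'   hashes; a mismatch raises a consistency error.
#' @return CO2 affinity in kcal/mol.
#' @export
co2_affinity <- function(g_adduct, g_nucleophile, g_co2,
                         settings_hashes = NULL) {
  if (!is.null(settings_hashes) &&
      length(unique(settings_hashes)) != 1) {
    abort_co2("free energies computed under different settings",
              "consistency_error")
  }
  -(g_adduct - g_nucleophile - g_co2) * HARTREE_TO_KCALMOL
}

.AGGS <- c("min", "max", "boltz", "lowE")

#' Build the descriptor table for a set of nucleophiles
#'
#' Guaranteed descriptor columns, each under the four ensemble
#' aggregations (suffixes `_min`, `_max`, `_boltz`, `_lowE`):
#' `homo` (HOMO energy, Hartree), `site_dipole` (Hirshfeld dipole magnitude
#' at CA, atomic units) and `buried_b1` (buried Sterimol B1 at CA averaged
#' over the C1/C2 axes, Angstrom). Additional per-conformer descriptors can
#' be supplied through `extra` as named functions
#' `(record, qm_result) -> value`. A row with missing conformer results is
#' flagged incomplete (`complete = FALSE`), never silently imputed.
#'
#' @param records named list of `nucleophile_record`s.
#' @param ensembles named list of `conformer_ensemble`s (same names).
#' @param qm_results named list; element i is a list of `qm_result`s, one
#'   per conformer of ensemble i (NULL marks a failed conformer).
#' @param temperature Kelvin, for Boltzmann weighting.
#' @param buried_radius,radii_table,angular_step steric descriptor settings.
#' @param extra named list of extra descriptor functions.
#' @param response optional named numeric vector of CO2 affinities
#'   (kcal/mol) to attach as the `co2a` column.
#' @return a data.frame (one row per nucleophile) with attribute
#'   `provenance` (temperature, buried radius, settings hash).
#' @export
build_descriptor_table <- function(records, ensembles, qm_results,
                                   temperature = 298.15, buried_radius = 5.5,
                                   radii_table = NULL, angular_step = 1,
                                   extra = list(), response = NULL) {
  ids <- names(records)
  stopifnot(!is.null(ids), all(ids %in% names(ensembles)),
            all(ids %in% names(qm_results)))
  base_desc <- list(
    homo = function(record, qr) qr$homo_energy,
    site_dipole = function(record, qr) site_dipole(qr, record$ca_index),
    buried_b1 = function(record, qr)
      site_b1(qr$optimized_coordinates, record, buried_radius, radii_table,
              angular_step)$b1)
  desc <- c(base_desc, extra)
  cols <- as.vector(outer(names(desc), .AGGS, paste, sep = "_"))
  rows <- lapply(ids, function(id) {
    qrs <- qm_results[[id]]
    n_conf <- length(ensembles[[id]]$conformers)
    ok <- length(qrs) == n_conf && !any(vapply(qrs, is.null, logical(1)))
    row <- stats::setNames(as.list(rep(NA_real_, length(cols))), cols)
    if (ok) {
      energies <- vapply(qrs, function(q) q$electronic_energy, numeric(1))
      for (dn in names(desc)) {
        vals <- vapply(qrs, function(q) desc[[dn]](records[[id]], q),
                       numeric(1))
        ag <- aggregate_ensemble(vals, energies, temperature, name = dn)
        for (a in .AGGS) row[[paste(dn, a, sep = "_")]] <- ag[[a]]
      }
    }
    c(list(id = id, complete = ok), row)
  })
  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (!is.null(response)) {
    tab$co2a <- unname(response[tab$id])
  }
  first_qr <- Filter(Negate(is.null), unlist(qm_results, recursive = FALSE))
  attr(tab, "provenance") <- list(
    temperature = temperature, buried_radius = buried_radius,
    angular_step = angular_step,
    settings_hash = if (length(first_qr)) first_qr[[1]]$settings_hash
                    else NA_character_)
  tab
}

#' Write / read a descriptor table with its metadata sidecar
#'
#' The table is written as CSV; units and provenance go to a JSON sidecar
#' at `<path>.meta.json`.
#'
#' @param table a descriptor table from [build_descriptor_table()].
#' @param path CSV path.
#' @return the path (write) or the table with provenance restored (read).
#' @export
write_descriptor_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  meta <- list(
    units = list(homo = "Hartree", site_dipole = "au", buried_b1 = "Angstrom",
                 co2a = "kcal/mol"),
    provenance = attr(table, "provenance"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_descriptor_table
#' @export
read_descriptor_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar)) {
    attr(tab, "provenance") <- jsonlite::read_json(sidecar)$provenance
  }
  tab
}
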