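#' Synthetic fixtures
#'
#' Pure generators (functions of case/spec + seed) for everything the test
#' suite and desk-scale demonstrations need: toy geometries whose Sterimol
#' values are known analytically or from the dense reference scan computed
#' at generation time, descriptor tables with planted linear structure, and
#' fake engine output files that embed requested property values verbatim.
#'
#' @name co2screen-fixtures
#' @keywords internal
NULL

#' Toy geometries with expected Sterimol values
#'
#' Cases: `"collinear"` (one substituent atom on the axis; analytic),
#' `"planar-T"` (three coplanar atoms; B1 analytic along the thin
#' direction), `"tetrahedral"` (methyl-like cap; reference scan),
#' `"distal-atom"` (compact cluster plus one atom at 7 Angstrom that alone
#' defines B5; reference scan, used for buried-Sterimol exclusion tests),
#' `"random-seeded"` (seeded random cloud; reference scan).
#'
#' @param case registry name.
#' @param seed seed for the random case.
#' @param n_atoms atom count for the random case (default 8).
#' @return list: coords, radii, attach, axis, expected (L, B1, B5), case.
#' @export
toy_geometry <- function(case = c("collinear", "planar-T", "tetrahedral",
                                  "distal-atom", "random-seeded"),
                         seed = 1, n_atoms = 8) {
  case <- match.arg(case)
  out <- switch(case,
    "collinear" = {
      coords <- rbind(c(0, 0, 0), c(1.09, 0, 0))
      radii <- c(1.70, 1.20)
      list(coords = coords, radii = radii, attach = 1L, axis = 2L,
           expected = list(L = 1.09 + 1.20, B1 = 1.20, B5 = 1.20))
    },
    "planar-T" = {
      ## axis along x; two wing atoms at +/- 2 Angstrom in y, all radius 1:
      ## thin direction is z, so B1 = 1 exactly; B5 = 2 + 1 = 3.
      coords <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(1.5, 2, 0), c(1.5, -2, 0))
      radii <- c(1.7, 1.0, 1.0, 1.0)
      list(coords = coords, radii = radii, attach = 1L, axis = 2L,
           expected = list(L = 1.5 + 1.0, B1 = 1.0, B5 = 3.0))
    },
    "tetrahedral" = {
      d <- 1.09; ang <- acos(-1 / 3)
      base <- rbind(c(0, 0, 0), c(1.54, 0, 0))
      hs <- t(vapply(0:2, function(k) {
        phi <- 2 * pi * k / 3
        c(1.54 + d * cos(pi - ang),
          d * sin(pi - ang) * cos(phi), d * sin(pi - ang) * sin(phi))
      }, numeric(3)))
      coords <- rbind(base, hs)
      radii <- c(1.70, 1.70, 1.20, 1.20, 1.20)
      list(coords = coords, radii = radii, attach = 1L, axis = 2L,
           expected = NULL)
    },
    "distal-atom" = {
      coords <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(1.2, 1.1, 0.3),
                      c(1.0, -0.9, -0.6), c(1.5, 7.0, 0))
      radii <- c(1.70, 1.70, 1.20, 1.20, 1.52)
      list(coords = coords, radii = radii, attach = 1L, axis = 2L,
           expected = NULL)
    },
    "random-seeded" = {
      radset <- c(1.20, 1.52, 1.55, 1.70)
      g <- with_local_seed(derive_seed(seed, 401L), {
        repeat {
          coords <- matrix(stats::runif(n_atoms * 3, -3, 3), n_atoms, 3)
          if (min(stats::dist(coords)) > 0.8) break
        }
        list(coords = coords,
             radii = sample(radset, n_atoms, replace = TRUE))
      })
      list(coords = g$coords, radii = g$radii, attach = 1L, axis = 2L,
           expected = NULL)
    })
  if (is.null(out$expected)) {
    ## oracle-at-generation-time: dense reference scan frozen into the fixture
    ref <- sterimol_scan(out$coords, out$radii, out$attach, out$axis)
    out$expected <- list(L = ref$L, B1 = ref$B1, B5 = ref$B5)
  }
  c(out, list(case = case, seed = seed))
}

#' Synthetic descriptor table with planted linear structure
#'
#' True features are independent standard normals; each decoy is correlated
#' with one true feature at `decoy_cor`. The response is the planted linear
#' combination plus Gaussian noise. With `noise_sigma = NULL` the noise is
#' calibrated analytically so the population R2 equals `target_r2`.
#' Generating parameters are embedded in the `planted` attribute so
#' recovery tests never hard-code them.
#'
#' @param n_samples number of rows (default 31).
#' @param true_coefficients named numeric vector of planted coefficients
#'   (default `c(x1 = 2, x2 = -1, x3 = 0.5)`).
#' @param n_decoys number of decoy features (default 9).
#' @param decoy_cor correlation of each decoy with its parent true feature
#'   (default 0.4).
#' @param noise_sigma response noise SD in kcal/mol, or NULL to calibrate.
#' @param target_r2 population R2 used when calibrating (default 0.95).
#' @param seed RNG seed.
#' @return data.frame with feature columns, a `co2a` response and an `id`
#'   column; attribute `planted` holds the generating spec.
#' @export
simulate_descriptor_table <- function(n_samples = 31,
                                      true_coefficients = c(x1 = 2, x2 = -1,
                                                            x3 = 0.5),
                                      n_decoys = 9, decoy_cor = 0.4,
                                      noise_sigma = NULL, target_r2 = 0.95,
                                      seed = 1) {
  stopifnot(abs(decoy_cor) < 1, is.null(noise_sigma) || noise_sigma >= 0)
  p_true <- length(true_coefficients)
  var_signal <- sum(true_coefficients^2)  # independent unit-variance truths
  if (is.null(noise_sigma)) {
    noise_sigma <- sqrt(var_signal * (1 - target_r2) / target_r2)
  }
  tabs <- with_local_seed(derive_seed(seed, 402L), {
    Xt <- matrix(stats::rnorm(n_samples * p_true), n_samples, p_true)
    Xd <- if (n_decoys > 0) {
      vapply(seq_len(n_decoys), function(k) {
        parent <- ((k - 1) %% p_true) + 1
        decoy_cor * Xt[, parent] +
          sqrt(1 - decoy_cor^2) * stats::rnorm(n_samples)
      }, numeric(n_samples))
    } else NULL
    y <- drop(Xt %*% true_coefficients) +
      stats::rnorm(n_samples, sd = noise_sigma)
    list(Xt = Xt, Xd = Xd, y = y)
  })
  X <- cbind(tabs$Xt, tabs$Xd)
  colnames(X) <- c(names(true_coefficients),
                   if (n_decoys > 0) sprintf("d%d", seq_len(n_decoys)))
  tab <- as.data.frame(X)
  tab$co2a <- tabs$y
  tab$id <- sprintf("s%02d", seq_len(n_samples))
  attr(tab, "planted") <- list(
    true_features = names(true_coefficients),
    true_coefficients = true_coefficients,
    noise_sigma = noise_sigma, decoy_cor = decoy_cor, seed = seed)
  tab
}

#' Write a fake engine output file embedding requested values
#'
#' Emits a parseable file in the requested dialect carrying the supplied
#' property values verbatim, for parser round-trip tests. `truncate_after`
#' cuts the file after the named section to exercise the parser's typed
#' errors.
#'
#' @param path output path.
#' @param elements element symbols.
#' @param coords Nx3 coordinates.
#' @param scf_energy,gibbs_energy energies in Hartree.
#' @param orbital_energies,occupancies orbital lists (equal length).
#' @param hirshfeld_charges per-atom charges.
#' @param hirshfeld_dipoles Nx3 atomic dipole vectors.
#' @param dialect `"qcout"` or `"proptable"`.
#' @param truncate_after optional section name after which to cut the file.
#' @return the path, invisibly.
#' @export
fake_engine_output <- function(path, elements, coords,
                               scf_energy = -100.0, gibbs_energy = -99.9,
                               orbital_energies = c(-0.5, -0.3, -0.14, 0.02),
                               occupancies = c(2, 2, 2, 0),
                               hirshfeld_charges = NULL,
                               hirshfeld_dipoles = NULL,
                               dialect = c("qcout", "proptable"),
                               truncate_after = NULL) {
  dialect <- match.arg(dialect)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.null(hirshfeld_charges)) hirshfeld_charges <- rep(-1 / n, n)
  if (is.null(hirshfeld_dipoles)) hirshfeld_dipoles <- matrix(0, n, 3)
  hirshfeld_dipoles <- as.matrix(hirshfeld_dipoles)
  lines <- if (dialect == "qcout") {
    c("# synthetic engine output (qcout dialect)",
      "[geometry]",
      sprintf("%s %.8f %.8f %.8f", elements, coords[, 1], coords[, 2],
              coords[, 3]),
      "[scf]",
      sprintf("energy_hartree %.10f", scf_energy),
      "[orbitals]",
      "# index occupancy energy_hartree",
      sprintf("%d %.1f %.10f", seq_along(orbital_energies), occupancies,
              orbital_energies),
      "[thermo]",
      sprintf("gibbs_hartree %.10f", gibbs_energy),
      "[hirshfeld]",
      "# element charge dx dy dz",
      sprintf("%s %.8f %.8f %.8f %.8f", elements, hirshfeld_charges,
              hirshfeld_dipoles[, 1], hirshfeld_dipoles[, 2],
              hirshfeld_dipoles[, 3]),
      "[end]")
  } else {
    c("# synthetic property file (proptable dialect)",
      paste("elements", paste(elements, collapse = " ")),
      paste("coordinates", paste(sprintf("%.8f", t(coords)), collapse = " ")),
      sprintf("electronic_energy %.10f", scf_energy),
      sprintf("gibbs_free_energy %.10f", gibbs_energy),
      paste("orbital_energies",
            paste(sprintf("%.10f", orbital_energies), collapse = " ")),
      sprintf("homo_index %d", max(which(occupancies > 0))),
      paste("hirshfeld_charges",
            paste(sprintf("%.8f", hirshfeld_charges), collapse = " ")),
      paste("hirshfeld_atomic_dipoles",
            paste(sprintf("%.8f", t(hirshfeld_dipoles)), collapse = " ")))
  }
  if (!is.null(truncate_after)) {
    cut <- grep(sprintf("^\\[%s\\]$", truncate_after), lines)
    if (length(cut)) lines <- lines[seq_len(min(cut))]
  }
  writeLines(lines, path)
  invisible(path)
}

#' Published screening-benchmark HOMO energies
#'
#' HOMO energies (Hartree) reported for the twelve top-ranked candidates of
#' the published screening study, bundled as a plain-text reference input
#' for exercising the screening filter on real reported values.
#'
#' @return data.frame with columns `id` and `epsilon_homo`.
#' @export
screening_homo_reference <- function() {
  utils::read.csv(system.file("extdata", "screening_homo_reference.csv",
                              package = "co2screen"),
                  colClasses = c("character", "numeric"))
}

#' Example carbanion SMILES sets
#'
#' `example_carbanions()` returns a small set of valid carbanion
#' nucleophiles matching the CA(C1,C2) pattern (deprotonated indene,
#' cyclopentadiene, fluorene, malononitrile, and relatives);
#' `example_smiles_file()` writes a mixed input file including invalid
#' lines for reject-path tests.
#'
#' @return data.frame with `smiles` and `id` columns.
#' @export
example_carbanions <- function() {
  data.frame(
    smiles = c("[CH-]1C=Cc2ccccc21",        # indenide
               "[CH-]1C=CC=C1",             # cyclopentadienide (localized)
               "[CH-]1c2ccccc2-c2ccccc21",  # fluorenide
               "[C-](C#N)C#N",              # malononitrile anion
               "[C-](C#N)c1ccccc1",         # phenylacetonitrile anion
               "CC(=O)[CH-]c1ccccc1",       # phenylacetone anion
               "[CH-](c1ccccc1)c1ccccc1",   # diphenylmethanide
               "CC(=O)[CH-]C(C)=O"),        # acetylacetonide
    id = c("indenide", "cp_anion", "fluorenide", "malononitrile_anion",
           "phenylacetonitrile_anion", "phenylacetone_anion",
           "diphenylmethanide", "acac_anion"),
    stringsAsFactors = FALSE)
}

#' @rdname example_carbanions
#' @param path file to write.
#' @param include_invalid append lines that must be rejected (a methide
#'   with no carbon neighbor, a neutral molecule, a nitrogen-flanked anion).
#' @export
example_smiles_file <- function(path, include_invalid = TRUE) {
  mols <- example_carbanions()
  lines <- paste(mols$smiles, mols$id)
  if (include_invalid) {
    lines <- c(lines,
               "[CH3-] methide",
               "c1ccccc1 benzene",
               "[N-]1C=CC=C1 pyrrolide")
  }
  writeLines(lines, path)
  invisible(path)
}
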