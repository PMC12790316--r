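#' Physical constants and element data
#'
#' Unit conventions used throughout: coordinates in Angstrom, energies in
#' Hartree internally, reaction energies reported in kcal/mol.
#'
#' @name co2screen-constants
#' @keywords internal
NULL

## Single definition site for the Hartree -> kcal/mol conversion.
HARTREE_TO_KCALMOL <- 627.509474

## Boltzmann constant in Hartree per Kelvin (CODATA k_B / E_h).
KB_HARTREE <- 3.166811563e-6

#' Convert energies between Hartree and kcal/mol
#'
#' @param x numeric vector of energies.
#' @return converted numeric vector.
#' @examples
#' hartree_to_kcalmol(-0.005)  # +(-3.1375...) kcal/mol
#' @export
hartree_to_kcalmol <- function(x) x * HARTREE_TO_KCALMOL

#' @rdname hartree_to_kcalmol
#' @export
kcalmol_to_hartree <- function(x) x / HARTREE_TO_KCALMOL

## Bondi van der Waals radii (Angstrom). Bondi, J. Phys. Chem. 68 (1964) 441;
## B from the Batsanov extension. Configurable via the `radii_table` argument
## of the descriptor functions.
.BONDI_RADII <- c(
  H = 1.20, He = 1.40,
  B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47, Ne = 1.54,
  Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Ar = 1.88,
  Se = 1.90, Br = 1.85, I = 1.98
)

.ATOMIC_NUMBERS <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, Se = 34, Br = 35, I = 53
)

## Pauling electronegativities for the mock backend's smooth charge model.
.ELECTRONEG <- c(
  H = 2.20, B = 2.04, C = 2.55, N = 3.04, O = 3.44, F = 3.98,
  Si = 1.90, P = 2.19, S = 2.58, Cl = 3.16, Se = 2.55, Br = 2.96, I = 2.66
)

#' Bondi van der Waals radii for a vector of element symbols
#'
#' @param elements character vector of element symbols.
#' @param table named numeric vector overriding the built-in Bondi set.
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radii <- function(elements, table = NULL) {
  tab <- .BONDI_RADII
  if (!is.null(table)) tab[names(table)] <- table
  r <- tab[elements]
  if (anyNA(r)) {
    abort_co2(
      sprintf("no van der Waals radius tabulated for element(s): %s",
              paste(unique(elements[is.na(r)]), collapse = ", ")),
      "radius_error")
  }
  unname(r)
}

atomic_numbers <- function(elements) {
  z <- .ATOMIC_NUMBERS[elements]
  if (anyNA(z)) {
    abort_co2(
      sprintf("unknown element symbol(s): %s",
              paste(unique(elements[is.na(z)]), collapse = ", ")),
      "element_error")
  }
  unname(z)
}

## Typed condition helper: every package error carries class
## co2screen_<what> + co2screen_error, so callers can branch on failure type.
abort_co2 <- function(message, class, ...) {
  stop(errorCondition(message,
                      class = c(paste0("co2screen_", class), "co2screen_error"),
                      ...))
}

## Derive a stage-specific RNG seed from the master seed. Documented scheme:
## seed_i = (seed * 2654435761 + stage_code) mod (2^31 - 1), Knuth
## multiplicative hashing; stage codes are fixed per call site.
derive_seed <- function(seed, stage_code) {
  as.integer((as.numeric(seed) * 2654435761 + stage_code) %% (2^31 - 1))
}

## Evaluate `expr` under a private RNG stream; restores global RNG state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
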