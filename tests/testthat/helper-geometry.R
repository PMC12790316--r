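# Shared geometry helpers for the test suite.

# Uniform random proper rotation matrix (seeded).
rand_rotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigid_motion <- function(coords, seed) {
  rot <- rand_rotation(seed)
  set.seed(seed + 1)
  shift <- rnorm(3, sd = 5)
  sweep(coords %*% rot, 2, shift, "+")
}

# A small carbanion input file shared across tests (cached embedding makes
# repeated parsing cheap).
fixture_smiles_file <- function(include_invalid = TRUE) {
  f <- tempfile(fileext = ".smi")
  example_smiles_file(f, include_invalid = include_invalid)
  f
}

fixture_records <- local({
  memo <- new.env()
  function() {
    if (is.null(memo$p)) {
      memo$p <- parse_smiles_input(fixture_smiles_file())
    }
    memo$p
  }
})

# Boltzmann constant in kcal/mol/K, independent of the package constant.
KB_KCAL <- 0.0019872041

with_seed_shuffle <- function(x, seed) {
  set.seed(seed + 9000)
  sample(x)
}
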