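mock_conf <- function(seed = 1, n = 6) {
  set.seed(seed)
  repeat {
    x <- matrix(rnorm(n * 3, sd = 2), n, 3)
    if (min(dist(x)) > 0.9) return(x)
  }
}

test_that("the mock backend is bit-deterministic and fully populated", {
  b <- mock_backend()
  els <- c("C", "C", "O", "N", "H", "H")
  co <- mock_conf(1)
  s <- qm_preset("screening")
  r1 <- run_backend(els, co, s, b)
  r2 <- mock_backend()$run(els, co, s, NULL)
  expect_identical(r1$homo_energy, r2$homo_energy)
  expect_identical(r1$hirshfeld_charges, r2$hirshfeld_charges)
  expect_identical(r1$orbital_energies, r2$orbital_energies)
  expect_true(is.finite(r1$gibbs_free_energy))
  expect_identical(r1$homo_energy, r1$orbital_energies[r1$homo_index])
  expect_lt(r1$homo_energy, r1$orbital_energies[r1$homo_index + 1])
  expect_length(r1$hirshfeld_charges, length(els))
  expect_equal(sum(r1$hirshfeld_charges), s$charge, tolerance = 1e-10)
})

test_that("mock scalar properties are invariant under rigid motion", {
  b <- mock_backend()
  els <- c("C", "C", "O", "N", "H", "H")
  co <- mock_conf(2)
  s <- qm_preset("screening")
  r1 <- run_backend(els, co, s, b)
  r2 <- run_backend(els, rigid_motion(co, 77), s, b)
  expect_equal(r1$homo_energy, r2$homo_energy, tolerance = 1e-10)
  expect_equal(r1$electronic_energy, r2$electronic_energy, tolerance = 1e-10)
  expect_equal(r1$gibbs_free_energy, r2$gibbs_free_energy, tolerance = 1e-10)
  expect_equal(r1$hirshfeld_charges, r2$hirshfeld_charges, tolerance = 1e-10)
  # dipole vectors rotate, magnitudes do not
  expect_equal(sqrt(rowSums(r1$hirshfeld_atomic_dipoles^2)),
               sqrt(rowSums(r2$hirshfeld_atomic_dipoles^2)),
               tolerance = 1e-10)
})

test_that("a single-atom input yields a valid degenerate result", {
  b <- mock_backend()
  r <- run_backend("C", matrix(0, 1, 3),
                   qm_settings(charge = -1), b)
  expect_s3_class(r, "qm_result")
  expect_length(r$hirshfeld_charges, 1)
  expect_true(all(r$hirshfeld_atomic_dipoles == 0))
})

test_that("identical reruns hit the cache and never re-invoke the engine", {
  b <- mock_backend()
  els <- c("C", "H")
  co <- rbind(c(0, 0, 0), c(1.09, 0, 0))
  s <- qm_preset("screening")
  run_backend(els, co, s, b)
  expect_identical(backend_calls(b), 1L)
  run_backend(els, co, s, b)
  expect_identical(backend_calls(b), 1L)  # cache hit
  run_backend(els, co, qm_preset("affinity"), b)
  expect_identical(backend_calls(b), 2L)  # different settings: new call
})

test_that("missing capabilities raise before any compute", {
  crippled <- qm_backend("partial", c("optimize", "single_point"),
                         function(...) stop("should never run"))
  expect_error(
    run_backend("C", matrix(0, 1, 3), qm_settings(), crippled),
    class = "co2screen_capability_error")
  expect_identical(backend_calls(crippled), 0L)
})

test_that("engine output parsing recovers planted values exactly", {
  f <- tempfile(fileext = ".out")
  fake_engine_output(f, elements = c("C", "H"),
                     coords = rbind(c(0, 0, 0), c(1.09, 0, 0)),
                     orbital_energies = c(-0.9, -0.5, -0.140, 0.02),
                     occupancies = c(2, 2, 2, 0),
                     hirshfeld_charges = c(-0.8, -0.2),
                     hirshfeld_dipoles = rbind(c(0.3, 0.4, 0), c(0, 0, 0)))
  r <- parse_engine_output(f, "qcout")
  expect_equal(r$homo_energy, -0.140)
  expect_identical(r$homo_index, 3L)
  expect_equal(site_dipole(r, 1), 0.5)  # 3-4-5 vector
  expect_equal(r$optimized_coordinates[2, 1], 1.09)
})

test_that("both built-in dialects agree on the same planted properties", {
  co <- rbind(c(0, 0, 0), c(0, 0, 1.2), c(1.1, 0, -0.3))
  args <- list(elements = c("C", "O", "N"), coords = co,
               scf_energy = -42.123, gibbs_energy = -42.001,
               orbital_energies = c(-1, -0.3, -0.15, 0.05),
               occupancies = c(2, 2, 2, 0),
               hirshfeld_charges = c(-0.5, -0.3, -0.2),
               hirshfeld_dipoles = matrix(0.1, 3, 3))
  f1 <- tempfile(); f2 <- tempfile()
  do.call(fake_engine_output, c(list(f1), args, dialect = "qcout"))
  do.call(fake_engine_output, c(list(f2), args, dialect = "proptable"))
  a <- parse_engine_output(f1, "qcout")
  b <- parse_engine_output(f2, "proptable")
  expect_equal(a$electronic_energy, b$electronic_energy)
  expect_equal(a$gibbs_free_energy, b$gibbs_free_energy)
  expect_equal(a$homo_energy, b$homo_energy)
  expect_equal(a$hirshfeld_charges, b$hirshfeld_charges)
})

test_that("truncated files raise parse errors naming the missing section", {
  co <- rbind(c(0, 0, 0), c(1.09, 0, 0))
  f <- tempfile()
  fake_engine_output(f, c("C", "H"), co, truncate_after = "scf")
  err <- tryCatch(parse_engine_output(f), error = function(e) e)
  expect_s3_class(err, "co2screen_parse_error")
  expect_match(conditionMessage(err), "end")
  expect_error(parse_engine_output(tempfile()),
               class = "co2screen_input_error")
  expect_error(parse_engine_output(f, dialect = "nonexistent"),
               class = "co2screen_dialect_error")
})

test_that("the file backend serves parsed results through the contract", {
  d <- tempfile(); dir.create(d)
  co <- rbind(c(0, 0, 0), c(1.09, 0, 0))
  fake_engine_output(file.path(d, "abc.out"), c("C", "H"), co,
                     orbital_energies = c(-0.5, -0.135, 0.1),
                     occupancies = c(2, 2, 0))
  b <- file_backend(d)
  r <- run_backend(c("C", "H"), co, qm_settings(), b, label = "abc")
  expect_equal(r$homo_energy, -0.135)
  expect_error(
    run_backend(c("C", "H"), co, qm_settings(), b, label = "missing"),
    class = "co2screen_missing_property")
})
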