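test_that("Boltzmann weights match closed forms and sum to one", {
  expect_equal(boltzmann_weights(c(-1, -1, -1), 298.15), rep(1 / 3, 3))
  # energy gap of kT*ln(2) gives 2:1 weighting
  kb_h <- 3.166811563e-6
  w <- boltzmann_weights(c(0, kb_h * 298.15 * log(2)), 298.15)
  expect_equal(w, c(2 / 3, 1 / 3), tolerance = 1e-12)
  # independent closed-form check in kcal/mol units
  de_kcal <- 1.0
  w2 <- boltzmann_weights(c(0, de_kcal / 627.509474), 298.15)
  expected <- 1 / (1 + exp(-de_kcal / (KB_KCAL * 298.15)))
  expect_equal(w2[1], expected, tolerance = 1e-6)
  expect_equal(sum(w2), 1, tolerance = 1e-12)
  expect_error(boltzmann_weights(numeric(0)), class = "co2screen_input_error")
})

test_that("Boltzmann weights reach the uniform and winner-take-all limits", {
  e <- c(0, 2e-3, 5e-3)  # Hartree
  expect_equal(boltzmann_weights(e, 1e6), rep(1 / 3, 3), tolerance = 1e-3)
  w0 <- boltzmann_weights(e, 1)
  expect_equal(w0, c(1, 0, 0), tolerance = 1e-12)
})

test_that("ensemble aggregation obeys its closed forms and ordering", {
  single <- aggregate_ensemble(2.5, -1, 298.15)
  expect_equal(unlist(single[c("min", "max", "boltz", "lowE")]),
               c(min = 2.5, max = 2.5, boltz = 2.5, lowE = 2.5))
  eq <- aggregate_ensemble(c(1, 3), c(-1, -1), 298.15)
  expect_equal(eq$boltz, 2)
  kb_h <- 3.166811563e-6
  tw <- aggregate_ensemble(c(1, 3), c(0, kb_h * 298.15 * log(2)), 298.15)
  expect_equal(tw$boltz, 5 / 3, tolerance = 1e-12)
  expect_equal(tw$lowE, 1)
  expect_error(aggregate_ensemble(1:3, 1:2), class = "co2screen_input_error")
  # min <= boltz <= max and min <= lowE <= max on random ensembles
  set.seed(31)
  for (k in 1:25) {
    v <- rnorm(5); e <- rnorm(5, sd = 2e-3)
    ag <- aggregate_ensemble(v, e, 298.15)
    expect_true(ag$min <= ag$boltz && ag$boltz <= ag$max)
    expect_true(ag$min <= ag$lowE && ag$lowE <= ag$max)
  }
})

test_that("collinear single-substituent Sterimol matches the analytic values", {
  g <- toy_geometry("collinear")
  s <- sterimol(g$coords, g$radii, g$attach, g$axis)
  expect_equal(s$L, 2.29)
  expect_equal(s$B1, 1.20)
  expect_equal(s$B5, 1.20)
})

test_that("planar-T Sterimol finds the thin direction analytically", {
  g <- toy_geometry("planar-T")
  s <- sterimol(g$coords, g$radii, g$attach, g$axis)
  expect_equal(s$B1, g$expected$B1, tolerance = 1e-9)
  expect_equal(s$B5, g$expected$B5, tolerance = 1e-9)
  expect_equal(s$L, g$expected$L, tolerance = 1e-9)
})

test_that("Sterimol values are invariant under rigid motion to 1e-9", {
  for (sd in 1:5) {
    g <- toy_geometry("random-seeded", seed = sd)
    s0 <- sterimol(g$coords, g$radii, g$attach, g$axis)
    s1 <- sterimol(rigid_motion(g$coords, 50 + sd), g$radii, g$attach, g$axis)
    expect_equal(s0$L, s1$L, tolerance = 1e-9)
    expect_equal(s0$B1, s1$B1, tolerance = 1e-9)
    expect_equal(s0$B5, s1$B5, tolerance = 1e-9)
  }
})

test_that("grid search agrees with the dense reference scan", {
  for (sd in 1:10) {
    g <- toy_geometry("random-seeded", seed = sd)
    a <- sterimol(g$coords, g$radii, g$attach, g$axis)
    b <- sterimol_scan(g$coords, g$radii, g$attach, g$axis)
    expect_lt(abs(a$B1 - b$B1), 1e-3)
    expect_lt(abs(a$B5 - b$B5), 1e-3)
    expect_equal(a$L, b$L, tolerance = 1e-12)
    expect_lte(a$B1, a$B5)
  }
})

test_that("buried Sterimol equals plain Sterimol when the sphere holds all atoms", {
  g <- toy_geometry("tetrahedral")
  plain <- sterimol(g$coords, g$radii, g$attach, g$axis)
  buried <- buried_sterimol(g$coords, g$radii, g$attach, g$axis,
                            buried_radius = 5.5)
  expect_equal(buried$B1, plain$B1, tolerance = 1e-12)
  expect_equal(buried$B5, plain$B5, tolerance = 1e-12)
})

test_that("excluding a distal atom shrinks B5 and leaves B1 unchanged", {
  g <- toy_geometry("distal-atom")
  plain <- sterimol(g$coords, g$radii, g$attach, g$axis)
  buried <- buried_sterimol(g$coords, g$radii, g$attach, g$axis,
                            buried_radius = 5.5)
  expect_lt(buried$B5, plain$B5)
  expect_equal(buried$B1, plain$B1, tolerance = 1e-9)
})

test_that("buried Sterimol composes as filter-then-Sterimol on random clouds", {
  for (sd in 11:16) {
    g <- toy_geometry("random-seeded", seed = sd)
    br <- 3.0
    buried <- buried_sterimol(g$coords, g$radii, g$attach, g$axis,
                              buried_radius = br)
    d <- sqrt(rowSums(sweep(g$coords, 2, g$coords[g$attach, ])^2))
    keep <- which(d <= br | seq_along(d) %in% c(g$attach, g$axis))
    oracle <- sterimol_scan(g$coords[keep, , drop = FALSE], g$radii[keep],
                            match(g$attach, keep), match(g$axis, keep))
    expect_lt(abs(buried$B1 - oracle$B1), 1e-3)
    expect_lt(abs(buried$B5 - oracle$B5), 1e-3)
  }
})

test_that("a fully excluded substituent raises a degenerate-geometry error", {
  g <- toy_geometry("collinear")
  expect_error(
    buried_sterimol(g$coords, g$radii, 1, 2, buried_radius = 0.5),
    class = "co2screen_degenerate_geometry")
})

test_that("site B1 is the mean of the two per-axis buried values", {
  rec <- fixture_records()$records$malononitrile_anion
  co <- rec$molecule$coords
  sb <- site_b1(co, rec)
  radii <- vdw_radii(rec$atoms$element)
  v1 <- buried_sterimol(co, radii, rec$ca_index, rec$c1_index, 5.5)$B1
  v2 <- buried_sterimol(co, radii, rec$ca_index, rec$c2_index, 5.5)$B1
  expect_equal(sb$b1, (v1 + v2) / 2)
  expect_equal(unname(sb$per_axis), c(v1, v2))
  # near-symmetric molecule: per-axis values close; mean bounded by them
  expect_gte(sb$b1, min(sb$per_axis))
  expect_lte(sb$b1, max(sb$per_axis))
})

test_that("CO2 affinity converts reaction free energies correctly", {
  expect_equal(co2_affinity(-100, -50, -50), 0)
  expect_equal(co2_affinity(-100.005, -50, -50), 0.005 * 627.509474)
  # monotone: more negative reaction energy means larger affinity
  dg <- seq(-0.02, 0.02, by = 0.005)
  aff <- co2_affinity(-50 - 38 + dg, -50, -38)
  expect_true(all(diff(aff) < 0))
  expect_error(co2_affinity(-1, -1, -1, settings_hashes = c("a", "b", "a")),
               class = "co2screen_consistency_error")
})

test_that("the descriptor table has the guaranteed shape and flags gaps", {
  p <- fixture_records()
  recs <- p$records[c("indenide", "malononitrile_anion")]
  ens <- lapply(recs, embed_ensemble, n_confs = 5, seed = 1)
  b <- mock_backend()
  s <- qm_preset("screening")
  qrs <- lapply(names(recs), function(id)
    lapply(ens[[id]]$conformers, function(cf)
      run_backend(recs[[id]]$molecule$elements, cf$coordinates, s, b)))
  names(qrs) <- names(recs)
  tab <- build_descriptor_table(recs, ens, qrs)
  feature_cols <- setdiff(names(tab), c("id", "complete"))
  expect_length(feature_cols, 12)  # 3 descriptors x 4 aggregations
  expect_true(all(tab$complete))
  expect_false(anyNA(tab[feature_cols]))
  # boltz columns bounded by min/max row-wise
  for (d in c("homo", "site_dipole", "buried_b1")) {
    expect_true(all(tab[[paste0(d, "_min")]] <= tab[[paste0(d, "_boltz")]] &
                    tab[[paste0(d, "_boltz")]] <= tab[[paste0(d, "_max")]]))
  }
  # a missing conformer result flags the row incomplete, never imputed
  qrs$indenide[[1]] <- NULL
  tab2 <- build_descriptor_table(recs, ens, qrs)
  expect_false(tab2$complete[tab2$id == "indenide"])
  expect_true(anyNA(tab2[tab2$id == "indenide", feature_cols]))
  expect_true(tab2$complete[tab2$id == "malononitrile_anion"])
})

test_that("descriptor tables round-trip through CSV with their sidecar", {
  tab <- simulate_descriptor_table(n_samples = 8, seed = 3)
  f <- tempfile(fileext = ".csv")
  attr(tab, "provenance") <- list(temperature = 298.15)
  write_descriptor_table(tab, f)
  back <- read_descriptor_table(f)
  expect_equal(back$co2a, tab$co2a, tolerance = 1e-12)
  expect_true(file.exists(paste0(f, ".meta.json")))
})
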