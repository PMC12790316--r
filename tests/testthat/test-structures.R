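test_that("deprotonated indene yields a record with CA flanked by two carbons", {
  rec <- fixture_records()$records$indenide
  expect_s3_class(rec, "nucleophile_record")
  expect_identical(rec$total_charge, -1L)
  atoms <- rec$atoms
  expect_identical(atoms$element[rec$ca_index], "C")
  expect_identical(atoms$formal_charge[rec$ca_index], -1L)
  expect_identical(atoms$element[rec$c1_index], "C")
  expect_identical(atoms$element[rec$c2_index], "C")
  expect_length(unique(c(rec$ca_index, rec$c1_index, rec$c2_index)), 3)
})

test_that("pattern violations are rejected with reasons, never dropped", {
  f <- tempfile(fileext = ".smi")
  writeLines(c("[CH-]1C=Cc2ccccc21 ok1",
               "[CH3-] methide",            # no carbon neighbors
               "[C-](C#N)C#N ok2",
               "c1ccccc1 benzene",          # neutral, no anionic carbon
               "[CH-](c1ccccc1)c1ccccc1 ok3"), f)
  p <- parse_smiles_input(f)
  expect_length(p$records, 3)
  expect_identical(nrow(p$rejects), 2L)
  expect_setequal(p$rejects$id, c("methide", "benzene"))
  expect_identical(p$rejects$reason[p$rejects$id == "benzene"],
                   "no carbanionic site")
  expect_identical(p$rejects$reason[p$rejects$id == "methide"],
                   "pattern mismatch")
  # conservation: every input line is accounted for
  expect_identical(length(p$records) + nrow(p$rejects), 5L)
})

test_that("a methide-only file returns zero records plus one reject", {
  f <- tempfile(fileext = ".smi")
  writeLines("[CH3-]", f)
  p <- parse_smiles_input(f)
  expect_length(p$records, 0)
  expect_identical(nrow(p$rejects), 1L)
})

test_that("empty or unreadable input raises typed errors", {
  f <- tempfile(fileext = ".smi")
  writeLines(c("", "# comment only"), f)
  expect_error(parse_smiles_input(f), class = "co2screen_empty_input")
  expect_error(parse_smiles_input(tempfile()), class = "co2screen_input_error")
})

test_that("detect_pattern errors distinguish absence, mismatch, ambiguity", {
  expect_error(detect_pattern(molecule_from_smiles("c1ccccc1")),
               class = "co2screen_pattern_absent")
  expect_error(detect_pattern(molecule_from_smiles("[CH3-]")),
               class = "co2screen_pattern_mismatch")
  # dianion with two equivalent carbanionic sites is never auto-picked
  expect_error(detect_pattern(molecule_from_smiles("[CH-](C#N)C[CH-]C#N")),
               class = "co2screen_pattern_ambiguous")
})

test_that("pattern detection is invariant under atom reordering of the SMILES", {
  a <- nucleophile_record(molecule_from_smiles("[CH-]1C=Cc2ccccc21"))
  b <- nucleophile_record(molecule_from_smiles("c1ccc2c(c1)C=C[CH-]2"))
  expect_identical(a$smiles, b$smiles)  # same canonical molecule
  # CA is the same structural atom: one H neighbor-carbon environment
  env <- function(r) sort(r$atoms$element[c(r$c1_index, r$c2_index)])
  expect_identical(env(a), env(b))
  expect_identical(a$atoms$formal_charge[a$ca_index],
                   b$atoms$formal_charge[b$ca_index])
})

test_that("deprotonation helper produces a valid carbanion from the C-H acid", {
  mol <- molecule_from_smiles("C1C=Cc2ccccc21 indene")  # neutral indene
  expect_error(detect_pattern(mol), class = "co2screen_pattern_absent")
  # find the ring CH2 carbon: a carbon with two H neighbors
  nbs <- co2screen:::neighbor_list(mol)
  ch2 <- which(vapply(seq_along(mol$elements), function(i)
    mol$elements[i] == "C" && sum(mol$elements[nbs[[i]]] == "H") == 2,
    logical(1)))[1]
  anion <- deprotonate(mol, ch2)
  rec <- nucleophile_record(anion)
  expect_identical(rec$total_charge, -1L)
  expect_identical(length(anion$elements), length(mol$elements) - 1L)
})
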