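test_that("SMILES libraries read with invalid entries skipped and counted", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO etoh", "c1ccccc1 benzene", "CC(=O)O acoh",
               "notasmiles)( bad", "CCN etn"), path)
  expect_warning(lib <- read_library(path), "skipped 1")
  expect_s3_class(lib, "molecule_records")
  expect_equal(nrow(lib), 4)
  expect_identical(attr(lib, "n_skipped"), 1L)
  expect_identical(lib$id, c("etoh", "benzene", "acoh", "etn"))
})

test_that("empty or fully invalid libraries raise an empty-library error", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(character(0), path)
  expect_error(read_library(path), class = "whalescreen_empty_library")
  writeLines(c("xx)( a", "yy)( b"), path)
  expect_error(suppressWarnings(read_library(path)),
               class = "whalescreen_empty_library")
  expect_error(read_library("/nonexistent/file.smi"),
               class = "whalescreen_io_error")
})

test_that("multi-fragment entries are reduced to the largest fragment", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines("CCN.Cl etn_hcl", path)
  expect_message(lib <- read_library(path), "largest fragment")
  expect_false(grepl(".", lib$smiles[1], fixed = TRUE))
})

test_that("preparation yields explicit hydrogens and conserved charge", {
  recs <- molecule_records(c("methane", "etoh", "mamm"),
                           c("C", "CCO", "C[NH3+]"))
  mols <- prepare_collection(recs, seed = 7)
  expect_length(mols, 3)
  expect_identical(nrow(attr(mols, "failures")), 0L)
  # methane: 5 atoms, neutral
  expect_identical(mols[["methane"]]$n_atoms, 5L)
  expect_lt(abs(sum(mols[["methane"]]$charges)), 0.01)
  # ethanol: 9 atoms with explicit H
  expect_identical(mols[["etoh"]]$n_atoms, 9L)
  # protonated methylamine: total charge ~ +1
  expect_lt(abs(sum(mols[["mamm"]]$charges) - 1), 0.01)
  # coordinates are finite, real 3D
  expect_true(all(is.finite(mols[["etoh"]]$coords)))
  expect_gt(max(dist(mols[["etoh"]]$coords)), 1)
})

test_that("ethanol oxygen carries the most negative Gasteiger charge, in agreement with an independent implementation", {
  mol <- prepare_molecule(list(id = "etoh", smiles = "CCO"), seed = 1)
  expect_identical(mol$elements[which.min(mol$charges)], "O")
  # independent oracle: OpenBabel's own Gasteiger implementation on the
  # same molecular graph
  lines <- whalescreen:::run_obabel_file(
    c("-omol2", "-h", "--partialcharge", "gasteiger"),
    input_lines = "CCO etoh")
  ob <- whalescreen:::parse_mol2(lines)[[1]]
  expect_identical(ob$elements[which.min(ob$charges)], "O")
})

test_that("preparation is deterministic and order-preserving", {
  recs <- molecule_records(c("a", "b", "c"), c("CCO", "CCCN", "c1ccccc1O"))
  m1 <- prepare_collection(recs, seed = 11)
  m2 <- prepare_collection(recs, seed = 11)
  expect_identical(lapply(m1, `[[`, "coords"), lapply(m2, `[[`, "coords"))
  expect_identical(lapply(m1, `[[`, "charges"), lapply(m2, `[[`, "charges"))
  expect_identical(names(m1), recs$id)
  # a different seed changes the embedded conformer
  m3 <- prepare_collection(recs, seed = 12)
  expect_false(identical(m1[["b"]]$coords, m3[["b"]]$coords))
})

test_that("multi-conformer embedding is deterministic and keeps one conformer", {
  rec <- molecule_records("rop", "CCCN1CCCCC1C(=O)Nc1c(C)cccc1C")
  m3 <- prepare_collection(rec, seed = 7, num_confs = 3)
  m3b <- prepare_collection(rec, seed = 7, num_confs = 3)
  expect_identical(m3[["rop"]]$coords, m3b[["rop"]]$coords)
  expect_identical(m3[["rop"]]$n_atoms, prepare_collection(rec, 7)[["rop"]]$n_atoms)
})

test_that("per-molecule seeds are stable under collection growth", {
  small <- molecule_records("a", "CCO")
  big <- molecule_records(c("zzz", "a"), c("CCCC", "CCO"))
  expect_identical(prepare_collection(small, seed = 5)[["a"]]$coords,
                   prepare_collection(big, seed = 5)[["a"]]$coords)
})

test_that("failures are reported per molecule, fatal only when all fail", {
  recs <- molecule_records(c("good", "bad"), c("CCO", "xx((yy"))
  mols <- prepare_collection(recs, seed = 3)
  expect_length(mols, 1)
  expect_identical(attr(mols, "failures")$id, "bad")
  allbad <- molecule_records("bad", "xx((yy")
  expect_error(prepare_collection(allbad, seed = 3),
               class = "whalescreen_preparation_error")
  expect_error(prepare_molecule(list(id = "bad", smiles = "xx((yy")),
               class = "whalescreen_preparation_error")
})

test_that("prepared molecules round-trip through SDF with charges", {
  recs <- molecule_records(c("etoh", "methane"), c("CCO", "C"))
  mols <- prepare_collection(recs, seed = 7)
  path <- withr::local_tempfile(fileext = ".sdf")
  write_prepared_sdf(mols, path)
  back <- read_prepared_sdf(path)
  expect_identical(names(back), names(mols))
  expect_equal(back[["etoh"]]$coords, mols[["etoh"]]$coords,
               tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(back[["etoh"]]$charges, mols[["etoh"]]$charges,
               tolerance = 1e-6)
  expect_identical(back[["etoh"]]$elements, mols[["etoh"]]$elements)
  # and the SDF is a valid library file for the reader
  lib <- read_library(path, format = "sdf")
  expect_equal(nrow(lib), 2)
})
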