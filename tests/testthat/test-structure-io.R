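test_that("single-residue fixture reads with the expected temperature factor", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_single_residue_pdb(path, b = 20)
  st <- read_structure(path)
  expect_equal(structure_chains(st), "A")
  expect_equal(nrow(st$residues), 1L)
  expect_equal(st$residues$tempfactor, 20)
  expect_equal(extract_sequence(st, "A"), "A")
})

test_that("two-chain fixture keeps chain order and sizes", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_two_chain_pdb(path)
  st <- read_structure(path)
  expect_equal(structure_chains(st), c("A", "B"))
  expect_equal(as.integer(table(st$residues$chain)[c("A", "B")]), c(3L, 2L))
  expect_equal(extract_sequence(st, "A"), "AGW")
  expect_equal(extract_sequence(st, "B"), "SV")
  expect_error(extract_sequence(st, "Z"), "not present")
})

test_that("predicted-model temperature factor is carried as confidence", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_single_residue_pdb(path, b = 91.5)
  st <- read_structure(path, source_kind = "predicted")
  expect_equal(st$source_kind, "predicted")
  expect_equal(st$residues$tempfactor, 91.5)
})

test_that("HETATM, waters and non-A altlocs are dropped; MSE becomes X", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "N",  "MSE", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "MSE", "A", 1, 1.5, 0, 0),
    pdb_atom_line(3, "CA", "GLY", "A", 2, 5, 0, 0),
    pdb_atom_line(4, "O",  "HOH", "A", 90, 9, 9, 9, record = "HETATM"),
    "END"), path)
  st <- read_structure(path)
  expect_equal(nrow(st$residues), 2L)
  expect_equal(extract_sequence(st, "A"), "XG")
  # altloc B dropped: mean tempfactor over kept atoms only
  lines <- readLines(path)
  alt_line <- pdb_atom_line(5, "CB", "GLY", "A", 2, 6, 0, 0, b = 99)
  substr(alt_line, 17, 17) <- "B"
  writeLines(c(lines[1:3], alt_line, "END"), path)
  st2 <- read_structure(path)
  expect_equal(st2$residues$tempfactor[2], 20)
})

test_that("file with no ATOM records errors", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "O", "HOH", "A", 1, 0, 0, 0, record = "HETATM"),
    "END"), path)
  expect_error(read_structure(path))
  expect_error(read_structure(file.path(tempdir(), "nope.pdb")),
               "not found")
})

test_that("classic DSSP bodies parse with breaks and blank SS handled", {
  path <- withr::local_tempfile(fileext = ".dssp")
  write_dssp_fixture(path, ss = c("H", "H", "E"), acc = c(100, 50, 20))
  d <- parse_dssp(path)
  expect_equal(d$ss8, c("H", "H", "E"))
  expect_equal(d$acc, c(100, 50, 20))
  expect_true(all(d$acc >= 0))

  write_dssp_fixture(path, ss = c(" ", "T"), acc = c(10, 20),
                     aa = c("A", "G"))
  expect_equal(parse_dssp(path)$ss8, c("-", "T"))

  write_dssp_fixture(path, ss = c("H", "E"), acc = c(10, 20),
                     aa = c("A", "G"), breaks = 2)
  expect_equal(nrow(parse_dssp(path)), 2L)

  writeLines(c("no header here", "    1    1 A M  H"), path)
  expect_error(parse_dssp(path), "header")
})

test_that("score-annotated structures round-trip to two decimals", {
  path <- withr::local_tempfile(fileext = ".pdb")
  out <- withr::local_tempfile(fileext = ".pdb")
  write_two_chain_pdb(path)
  st <- read_structure(path)
  expect_error(write_score_structure(st, c(0.1, 0.2), out),
               "one score per residue")
  scores <- c(0.25, 0.5, 0, 1, 0.333)
  write_score_structure(st, scores, out)
  back <- read_structure(out)
  expect_equal(back$residues$tempfactor / 100, scores, tolerance = 1e-12)
  # extremes format exactly
  txt <- readLines(out)
  expect_true(any(grepl("100.00", txt, fixed = TRUE)))
  expect_true(any(grepl("  0.00", txt, fixed = TRUE)))
})

test_that("read -> write -> read preserves residues, order and sequence", {
  path <- withr::local_tempfile(fileext = ".pdb")
  out <- withr::local_tempfile(fileext = ".pdb")
  write_two_chain_pdb(path)
  st <- read_structure(path)
  write_structure(st, out)
  st2 <- read_structure(out)
  expect_equal(st2$residues$resid, st$residues$resid)
  expect_equal(st2$residues$chain, st$residues$chain)
  expect_equal(st2$residues$tempfactor, st$residues$tempfactor)
  expect_equal(extract_sequence(st2, "A"), extract_sequence(st, "A"))
})
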