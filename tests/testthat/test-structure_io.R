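test_that("SDF records are parsed faithfully", {
  path <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c(
    "toy", "  test", "",
    "  2  1  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.2000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  2  0",
    "M  END",
    "$$$$"), path)
  lig <- read_ligand_sdf(path)
  expect_equal(nrow(lig$atoms), 2L)
  expect_equal(lig$atoms$element, c("C", "O"))
  expect_equal(lig$atoms$x, c(0, 1.2))
  expect_equal(nrow(lig$bonds), 1L)
  expect_equal(lig$bonds$order, 2L)
  expect_equal(lig$name, "toy")
})

test_that("formal charges come from M CHG lines", {
  path <- withr::local_tempfile(fileext = ".sdf")
  lig <- benzamidine_like()
  write_ligand_sdf(lig, path)
  back <- read_ligand_sdf(path)
  expect_equal(back$atoms$charge, lig$atoms$charge)
})

test_that("a counts line inconsistent with the atom block is a parse error", {
  path <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c(
    "bad", "", "",
    "  3  1  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0",
    "    1.2000    0.0000    0.0000 O   0  0",
    "  1  2  1  0",
    "M  END",
    "$$$$"), path)
  expect_error(read_ligand_sdf(path), "atom line|declares")
})

test_that("degenerate SDF inputs give clear errors", {
  path <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c("empty", "", "",
               "  0  0  0  0  0  0  0  0  0  0999 V2000", "M  END", "$$$$"),
             path)
  expect_error(read_ligand_sdf(path), "empty molecule")
  writeLines(c("v3", "", "",
               "  0  0  0  0  0  0  0  0  0  0999 V3000", "M  END", "$$$$"),
             path)
  expect_error(read_ligand_sdf(path), "V3000")
  expect_error(read_ligand_sdf(file.path(tempdir(), "nope.sdf")), "no such file")
})

test_that("multi-record SDF defaults to the first record and honors the index", {
  path <- withr::local_tempfile(fileext = ".sdf")
  ds <- tiny_dataset(2)
  l1 <- ds$samples[[1]]$ligand
  l2 <- ds$samples[[2]]$ligand
  con <- file(path, "w")
  writeLines(c(readLines(write_ligand_sdf(l1, withr::local_tempfile())),
               readLines(write_ligand_sdf(l2, withr::local_tempfile()))), con)
  close(con)
  expect_equal(nrow(read_ligand_sdf(path)$atoms), nrow(l1$atoms))
  expect_equal(nrow(read_ligand_sdf(path, record = 2)$atoms), nrow(l2$atoms))
  expect_error(read_ligand_sdf(path, record = 3), "2 record")
})

test_that("synthetic ligands round-trip through SDF", {
  for (seed in c(3, 17)) {
    ds <- tiny_dataset(1, seed = seed)
    lig <- ds$samples[[1]]$ligand
    path <- withr::local_tempfile(fileext = ".sdf")
    write_ligand_sdf(lig, path)
    back <- read_ligand_sdf(path)
    expect_equal(back$atoms$element, lig$atoms$element)
    expect_equal(back$bonds, lig$bonds)
    expect_lt(max(abs(as.matrix(back$atoms[, c("x", "y", "z")]) -
                        as.matrix(lig$atoms[, c("x", "y", "z")]))), 1e-3)
  }
})

test_that("PDB pockets parse with waters excluded and HETATM dropped", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "HETATM    3  O   HOH A 101       9.000   0.000   0.000  1.00  0.00           O",
    "HETATM    4  FE  HEM A 102       5.000   5.000   0.000  1.00  0.00          FE",
    "END"), path)
  poc <- read_pocket_pdb(path)
  expect_equal(poc$sequence, "AG")
  expect_equal(nrow(poc$atoms), 2L)
  expect_error(read_pocket_pdb({
    p2 <- withr::local_tempfile(fileext = ".pdb")
    writeLines("END", p2); p2
  }), "ATOM")
})

test_that("first altLoc variant is kept", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       0.500   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "END"), path)
  poc <- read_pocket_pdb(path)
  expect_equal(nrow(poc$atoms), 2L)
  expect_equal(poc$atoms$x[1], 0)
})

test_that("synthetic pockets round-trip through PDB", {
  ds <- tiny_dataset(1, seed = 23)
  poc <- ds$samples[[1]]$pocket
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pocket_pdb(poc, path)
  back <- read_pocket_pdb(path)
  expect_equal(back$residues$resid, poc$residues$resid)
  expect_equal(back$sequence, poc$sequence)
  expect_lt(max(abs(as.matrix(back$atoms[, c("x", "y", "z")]) -
                      as.matrix(poc$atoms[, c("x", "y", "z")]))), 1e-3)
})

test_that("pocket sequences map nonstandard residues per the fixed table", {
  mk <- function(resids) {
    n <- length(resids)
    new_pocket(data.frame(resid = resids, chain = "A", resno = seq_len(n)),
               data.frame(element = "C", x = 3.8 * seq_len(n), y = 0, z = 0,
                          res_index = seq_len(n)))
  }
  expect_equal(pocket_sequence(mk(c("MET", "LYS"))), "MK")
  expect_message(s <- pocket_sequence(mk(c("ALA", "MSE", "GLY", "UNK"))),
                 "UNK")
  expect_equal(s, "AMG")
  expect_equal(pocket_sequence(mk(c("SEC", "ALA"))), "CA")
  expect_error(suppressMessages(pocket_sequence(mk(c("UNK")))), "empty sequence")
  expect_equal(nchar(pocket_sequence(mk(c("ALA", "GLY", "TRP")))), 3L)
})

test_that("PDBbind-style index files parse", {
  path <- withr::local_tempfile()
  writeLines(c("# PDBbind index", "# id resolution year pK",
               "1abc  2.00  2016  6.42  // Kd=380nM",
               "2xyz  1.80  2018  8.10  // Ki=8nM"), path)
  idx <- read_affinity_index(path)
  expect_equal(idx$id, c("1abc", "2xyz"))
  expect_equal(idx$pk, c(6.42, 8.10))
})
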