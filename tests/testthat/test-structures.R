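# Atom/residue typing and structure parsing.

test_that("ligand element classification covers the 8 classes", {
  expect_identical(classifyLigandAtom(c("C", "H", "O", "N", "P", "S")),
                   c("C", "H", "O", "N", "P", "S"))
  expect_identical(classifyLigandAtom(c("F", "Cl", "Br", "I")),
                   rep("HAL", 4L))
  expect_identical(classifyLigandAtom(c("Fe", "Zn", "Se", "B")),
                   rep("DU", 4L))
  expect_identical(classifyLigandAtom("D"), "H")     # deuterium as hydrogen
  expect_identical(classifyLigandAtom("cl"), "HAL")  # case-insensitive
  expect_warning(out <- classifyLigandAtom("Xx"), "unrecognized")
  expect_identical(out, "DU")
})

test_that("residue classification is total: 20 standard codes plus OTH", {
  std <- setdiff(residueClasses(), "OTH")
  expect_identical(classifyResidue(std), std)
  expect_identical(classifyResidue(c("HOH", "WAT", "MSE", "ZN", "NAG", "X")),
                   rep("OTH", 6L))
  expect_length(residueClasses(), 21L)
  expect_length(ligandAtomClasses(), 8L)
  expect_identical(length(residueClasses()) * length(ligandAtomClasses()),
                   168L)
})

makeTestPdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   GLY A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA AGLY A   1       2.000   2.000   3.000  0.40  0.00           C",
    "ATOM      3  CA BGLY A   1       2.500   2.000   3.000  0.60  0.00           C",
    "ATOM      4  H   GLY A   1       1.500   2.500   3.000  1.00  0.00           H",
    "ATOM      5  N   GLY A   2       4.000   2.000   3.000  1.00  0.00           N",
    "HETATM    6  O   HOH A 101       8.000   8.000   8.000  1.00  0.00           O",
    "HETATM    7 ZN    ZN A 102       9.000   9.000   9.000  1.00  0.00          ZN",
    "END"), path)
  path
}

test_that("PDB parsing types residues, keeps waters/ions as OTH, drops H", {
  f <- makeTestPdb(tempfile(fileext = ".pdb"))
  p <- readProteinPDB(f)
  expect_identical(nrow(p$residues), 4L)
  expect_identical(p$residues$residueClass, c("GLY", "GLY", "OTH", "OTH"))
  # water and the zinc ion are independent single-atom OTH residues
  expect_identical(p$residues$nAtoms[3:4], c(1L, 1L))
  # hydrogens never reach the heavy-atom table
  expect_identical(sum(p$residues$nAtoms), nrow(p$residueAtoms))
  expect_identical(nrow(p$residueAtoms), 5L)
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  f <- makeTestPdb(tempfile(fileext = ".pdb"))
  p <- readProteinPDB(f)
  # GLY 1 CA: occupancies 0.40 (x=2.0) vs 0.60 (x=2.5) -> keep 2.5
  g1 <- p$residueAtoms[p$residueAtoms$residue == 1L, ]
  expect_true(any(abs(g1$x - 2.5) < 1e-9))
  expect_false(any(abs(g1$x - 2.0) < 1e-9))
})

test_that("all-hydrogen residues are dropped; empty structures error", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  H   GLY A   2       1.500   2.500   3.000  1.00  0.00           H",
    "END"), f)
  expect_warning(p <- readProteinPDB(f), "without heavy atoms")
  expect_identical(p$residues$rawName, "ALA")

  f2 <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  H   GLY A   1       1.500   2.500   3.000  1.00  0.00           H",
    "END"), f2)
  expect_error(suppressWarnings(readProteinPDB(f2)), "empty structure")
  expect_error(readProteinPDB(tempfile()), "not found")
})

test_that("keepHet = FALSE drops HETATM groups entirely", {
  f <- makeTestPdb(tempfile(fileext = ".pdb"))
  p <- readProteinPDB(f, keepHet = FALSE)
  expect_identical(p$residues$residueClass, c("GLY", "GLY"))
})

test_that("ligand parsing keeps hydrogens and types every atom", {
  f <- tempfile(fileext = ".mol2")
  lig <- data.frame(element = c("C", "C", "O", "H", "Br"),
                    atomClass = c("C", "C", "O", "H", "HAL"),
                    x = 1:5, y = 0, z = 0)
  writeLigandMOL2(lig, f)
  got <- readLigand(f)
  expect_identical(got$atomClass, c("C", "C", "O", "H", "HAL"))
  expect_equal(got$x, 1:5, tolerance = 1e-6)
  expect_error(readLigand(tempfile(fileext = ".mol2")), "not found")
  empty <- tempfile(fileext = ".mol2")
  writeLines("", empty)
  expect_error(readLigand(empty))
})

test_that("SDF and MOL2 encodings of one molecule agree", {
  set.seed(5)
  lig <- ligandAtoms(generateComplex(syntheticSpec(seed = 5L), 1L))
  f1 <- tempfile(fileext = ".mol2")
  f2 <- tempfile(fileext = ".sdf")
  writeLigandMOL2(lig, f1)
  writeLigandSDF(lig, f2)
  a <- readLigand(f1)
  b <- readLigand(f2)
  expect_identical(sort(a$atomClass), sort(b$atomClass))
  expect_identical(sort(toupper(a$element)), sort(toupper(b$element)))
  expect_equal(a[, c("x", "y", "z")], b[, c("x", "y", "z")],
               tolerance = 1e-3)
})

test_that("synthetic fixtures round-trip through the parsers", {
  spec <- syntheticSpec(seed = 9L)
  d <- tempfile()
  cx <- generateComplex(spec, 3L, dir = d)
  back <- readComplex(file.path(d, "s0003_protein.pdb"),
                      file.path(d, "s0003_ligand.mol2"),
                      complexId = complexId(cx))
  expect_identical(nrow(residues(back)), nrow(residues(cx)))
  expect_identical(residues(back)$residueClass, residues(cx)$residueClass)
  expect_identical(nrow(residueAtoms(back)), nrow(residueAtoms(cx)))
  expect_lt(max(abs(as.matrix(residueAtoms(back)[, c("x", "y", "z")]) -
                    as.matrix(residueAtoms(cx)[, c("x", "y", "z")]))),
            1e-3)
  expect_identical(sort(ligandAtoms(back)$atomClass),
                   sort(ligandAtoms(cx)$atomClass))
})

test_that("ComplexStructure validity rejects broken objects", {
  spec <- syntheticSpec(seed = 2L)
  cx <- generateComplex(spec, 1L)
  bad <- residueAtoms(cx)
  bad$x[1] <- NA
  expect_error(complexStructure("x", list(residues = residues(cx),
                                          residueAtoms = bad),
                                ligandAtoms(cx)),
               "non-finite")
  expect_error(complexStructure("x", list(residues = residues(cx)[0, ],
                                          residueAtoms = residueAtoms(cx)),
                                ligandAtoms(cx)))
})
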