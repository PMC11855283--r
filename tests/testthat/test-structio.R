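test_that("PDB parsing round-trips fixtures and applies the altloc rule", {
  s <- readPDBText(alaninePDB(), role = "receptor")
  expect_s4_class(s, "AbStructure")
  expect_equal(nrow(residueKeys(s)), 1)
  expect_equal(nrow(atomTable(s)), 5)
  expect_true(all(atomTable(s)$isHeavy))

  # hydrogens retained, flagged non-heavy
  withH <- paste(alaninePDB(), collapse = "\n")
  withH <- sub("END", paste(
    "ATOM      6  H   ALA A   1       0.300  -0.900   0.200  1.00  0.00           H",
    "END", sep = "\n"), withH)
  sH <- readPDBText(withH, role = "receptor")
  expect_equal(sum(!atomTable(sH)$isHeavy), 1)
  expect_equal(nrow(atomTable(sH)), 6)

  # altloc: keep the higher-occupancy conformer of CA only
  alt <- paste(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   1       1.400   0.100   0.000  0.60  0.00           C",
    "END", sep = "\n")
  sA <- readPDBText(alt, role = "receptor")
  expect_equal(nrow(atomTable(sA)), 2)
  kept <- atomTable(sA)[atomTable(sA)$name == "CA", ]
  expect_equal(kept$occupancy, 0.60)

  expect_error(readPDBText("REMARK nothing here", role = "receptor"),
               "no ATOM/HETATM")

  # write/read fidelity to format precision
  tf <- tempfile(fileext = ".pdb")
  writePDB(s, tf)
  s2 <- readPDB(tf, role = "receptor")
  expect_equal(atomTable(s2)$x, atomTable(s)$x, tolerance = 1e-3)
  expect_equal(atomTable(s2)$name, atomTable(s)$name)
})

test_that("cleaning removes waters, ions and ligands and is idempotent", {
  s <- readPDBText(dirtyPDB(nProtein = 10, nWater = 2, ion = TRUE),
                   role = "receptor")
  expect_equal(nrow(residueKeys(s)), 13)
  cl <- cleanStructure(s)
  expect_equal(nrow(residueKeys(cl)), 10)
  expect_true(all(atomTable(cl)$resname == "GLY"))
  # idempotent
  expect_identical(atomTable(cleanStructure(cl)), atomTable(cl))
  # no hetero records: identity
  pure <- readPDBText(dirtyPDB(nWater = 0, ion = FALSE), role = "receptor")
  expect_identical(atomTable(cleanStructure(pure)), atomTable(pure))
  # only waters: unusable
  waters <- readPDBText(dirtyPDB(nProtein = 0, nWater = 3, ion = FALSE),
                        role = "receptor")
  expect_error(cleanStructure(waters), "empty after cleaning")
})

test_that("binding labels follow the <= 4.5 A heavy-atom convention", {
  mk <- function(d) {
    rec <- randomStructure(1, seed = 1)
    rec@atoms$x <- 0; rec@atoms$y <- 0; rec@atoms$z <- 0
    ant <- randomStructure(1, role = "antigen", seed = 2)
    ant@atoms$x <- d; ant@atoms$y <- 0; ant@atoms$z <- 0
    labelBindingResidues(rec, ant)
  }
  expect_true(bindingVector(mk(4.4))[[1]])
  expect_false(bindingVector(mk(4.6))[[1]])
  expect_true(bindingVector(mk(4.5))[[1]])  # boundary: <= convention

  # hydrogens never contribute to the distance
  rec <- readPDBText(paste(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  H   GLY A   1       5.000   0.000   0.000  1.00  0.00           H",
    "END", sep = "\n"), role = "receptor")
  ant <- randomStructure(1, role = "antigen", seed = 3)
  ant@atoms$x <- 7; ant@atoms$y <- 0; ant@atoms$z <- 0
  expect_false(bindingVector(labelBindingResidues(rec, ant))[[1]])
})

test_that("labels equal the brute-force oracle and are rigid-invariant", {
  for (seed in 1:5) {
    rec <- randomStructure(sample(20:60, 1), seed = seed)
    ant <- randomStructure(sample(20:60, 1), role = "antigen", seed = seed + 100)
    for (cutoff in c(3, 4.5, 6)) {
      got <- bindingVector(labelBindingResidues(rec, ant, cutoff = cutoff))
      expect_identical(got, bruteForceLabels(rec, ant, cutoff = cutoff))
    }
    tf <- rigidTransform(seed)
    got0 <- bindingVector(labelBindingResidues(rec, ant))
    got1 <- bindingVector(labelBindingResidues(applyRigid(rec, tf),
                                               applyRigid(ant, tf)))
    expect_identical(got0, got1)
  }
})

test_that("sanity check mirrors the labels and gates non-contact pairs", {
  toy <- makeToyComplex(toyComplexSpec(receptorResidues = 6, interface = 3))
  expect_true(sanityCheck(toy$receptor, toy$antigen))
  far <- makeToyComplex(toyComplexSpec(receptorResidues = 6,
                                       interface = integer(0)))
  expect_false(sanityCheck(far$receptor, far$antigen))
  # equivalence with any(label)
  for (seed in 1:3) {
    rec <- randomStructure(30, seed = seed)
    ant <- randomStructure(30, role = "antigen", seed = seed + 50)
    expect_identical(sanityCheck(rec, ant),
                     any(bindingVector(labelBindingResidues(rec, ant))))
  }
  # exact-cutoff contact counts as contact
  rec <- randomStructure(1, seed = 1); rec@atoms[c("x", "y", "z")] <- 0
  ant <- randomStructure(1, role = "antigen", seed = 2)
  ant@atoms$x <- 4.5; ant@atoms$y <- 0; ant@atoms$z <- 0
  expect_true(sanityCheck(rec, ant))
})

test_that("chain selection keeps identifiers intact", {
  toy <- makeToyComplex(toyComplexSpec(receptorResidues = 4, interface = 2,
                                       chain = "H"))
  expect_error(selectChains(toy$receptor, "L"), "no atoms left")
  same <- selectChains(toy$receptor, "H")
  expect_identical(atomTable(same), atomTable(toy$receptor))
})
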