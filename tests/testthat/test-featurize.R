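test_that("balanced sampling is balanced, capped and deterministic", {
  toy <- makeToyComplex(toyComplexSpec(receptorResidues = 8, interface = c(2, 5)))
  cloud <- generateSurface(toy$receptor)
  sp <- balancedSample(cloud, toy$antigen, n = 20, seed = 4)
  expect_equal(length(sp$positives), 20)
  expect_equal(length(sp$negatives), 20)
  # capped branch: ask for more positives than exist
  sp2 <- balancedSample(cloud, toy$antigen, n = 10000, seed = 4)
  expect_lt(length(sp2$positives), 10000)
  expect_equal(length(sp2$positives), length(sp2$negatives))
  # positives really are within the cutoff, negatives beyond it
  lab <- surfacePointLabels(cloud, toy$antigen)
  expect_true(all(lab[sp2$positives]))
  expect_false(any(lab[sp2$negatives]))
  # determinism
  sp3 <- balancedSample(cloud, toy$antigen, n = 20, seed = 4)
  expect_identical(sp$positives, sp3$positives)
  expect_identical(sp$negatives, sp3$negatives)
  # zero positives: empty result plus warning
  far <- makeToyComplex(toyComplexSpec(receptorResidues = 4,
                                       interface = integer(0), decoySep = 30))
  cloudF <- generateSurface(far$receptor)
  expect_warning(spF <- balancedSample(cloudF, far$antigen), "unusable")
  expect_length(spF$positives, 0)
})

test_that("atom features have 22 channels with correct typing", {
  ala <- readPDBText(alaninePDB(), role = "receptor")
  f <- atomFeatures(ala)
  expect_equal(ncol(f), 22)
  expect_equal(nrow(f), 5)
  # exactly one atom-class channel set per classifiable atom
  expect_equal(unname(rowSums(f[, 1:9])), rep(1, 5))
  O <- f[atomTable(ala)$name == "O", ]
  expect_equal(unname(O["classO"]), 1)
  expect_equal(unname(O["acceptor"]), 1)
  expect_equal(unname(O["aromatic"]), 0)
  expect_equal(unname(O["hybridization"]), 2)   # carbonyl sp2
  expect_equal(unname(O["heavyValence"]), 1)    # bonded to C only
  # CB: carbon bonded only to carbon -> hydrophobic
  CB <- f[atomTable(ala)$name == "CB", ]
  expect_equal(unname(CB["hydrophobic"]), 1)
  # CA: bonded to N -> not hydrophobic; heterovalence 1
  CA <- f[atomTable(ala)$name == "CA", ]
  expect_equal(unname(CA["hydrophobic"]), 0)
  expect_equal(unname(CA["heterovalence"]), 1)
})

test_that("halogens classify and PQR only moves force-field channels", {
  cl <- paste(
    "ATOM      1 CL   LIG A   1       0.000   0.000   0.000  1.00  0.00          CL",
    "END", sep = "\n")
  s <- readPDBText(cl, role = "receptor")
  f <- atomFeatures(s)
  expect_equal(unname(f[1, "classHalogen"]), 1)

  ala <- readPDBText(alaninePDB(), role = "receptor")
  f0 <- atomFeatures(ala)
  pqr <- paste(
    "ATOM      1  N   ALA     1       0.000   0.000   0.000 -0.3000 1.6000",
    "ATOM      2  CA  ALA     1       1.458   0.000   0.000  0.1000 1.9000",
    "ATOM      3  C   ALA     1       2.009   1.420   0.000  0.5000 1.9000",
    "ATOM      4  O   ALA     1       1.251   2.390   0.000 -0.5000 1.6000",
    "ATOM      5  CB  ALA     1       2.000  -0.750  -1.250 -0.1000 2.0000",
    sep = "\n")
  tf <- tempfile(fileext = ".pqr")
  writeLines(pqr, tf)
  f1 <- atomFeatures(ala, pqrAmber = tf)
  expect_identical(f0[, 1:18], f1[, 1:18])
  expect_equal(unname(f1[, "amberCharge"]), c(-0.3, 0.1, 0.5, -0.5, -0.1))
  expect_equal(unname(f1[, "amberRadius"]), c(1.6, 1.9, 1.9, 1.6, 2.0))
  # untouched force field keeps the packaged values
  expect_identical(f0[, "charmmCharge"], f1[, "charmmCharge"])
  # PQR miss -> zeros and a logged count
  writeLines(pqr[1], tf)
  writeLines(strsplit(pqr, "\n")[[1]][1:2], tf)
  expect_message(f2 <- atomFeatures(ala, pqrAmber = tf), "missing from AMBER")
  expect_equal(unname(f2[3:5, "amberCharge"]), c(0, 0, 0))
})

test_that("local frames are orthonormal right-handed with normal as z", {
  expect_equal(localFrame(c(0, 0, 1)), diag(3), tolerance = 1e-12)
  expect_error(localFrame(c(0, 0, 0)), "zero-norm")
  set.seed(42)
  for (i in 1:200) {
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    R <- localFrame(n)
    expect_equal(R %*% t(R), diag(3), tolerance = 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
    expect_equal(unname(R[3, ]), n, tolerance = 1e-9)
  }
})

test_that("voxelization places, accumulates, and captures the 20 A ball", {
  toy <- makeToyComplex(toyComplexSpec(receptorResidues = 6, interface = 3))
  f <- atomFeatures(toy$receptor)
  # empty neighbourhood
  g0 <- voxelize(toy$receptor, c(500, 500, 500), diag(3), f, size = 9)
  expect_true(all(g0 == 0))
  expect_equal(dim(g0), c(9, 9, 9, 22))
  # single carbon at the centre: its class channel counts 1 in the mid voxel
  one <- randomStructure(1, seed = 5)
  fo <- atomFeatures(one)
  g1 <- voxelize(one, c(one@atoms$x, one@atoms$y, one@atoms$z), diag(3), fo,
                 size = 9)
  expect_equal(g1[5, 5, 5, 2], 1)  # classC channel
  expect_equal(sum(g1[, , , 2]), 1)
  # translation invariance is bit-exact
  ctr <- c(8, 1, 3)
  gA <- voxelize(toy$receptor, ctr, diag(3), f, size = 15)
  shifted <- toy$receptor
  shifted@atoms$x <- shifted@atoms$x + 7.3
  shifted@atoms$y <- shifted@atoms$y - 2.1
  shifted@atoms$z <- shifted@atoms$z + 4.4
  fS <- atomFeatures(shifted)
  gB <- voxelize(shifted, ctr + c(7.3, -2.1, 4.4), diag(3), fS, size = 15)
  expect_identical(gA, gB)
  # every heavy atom within 20 A of the centre lands in a 41-grid voxel
  rs <- randomStructure(80, box = 36, seed = 9)
  fr <- atomFeatures(rs)
  ctr <- c(18, 18, 18)
  g <- voxelize(rs, ctr, localFrame(c(0.3, -0.5, 0.81) / sqrt(0.3^2 + 0.5^2 + 0.81^2)),
                fr, size = 41)
  d <- sqrt((rs@atoms$x - ctr[1])^2 + (rs@atoms$y - ctr[2])^2 +
              (rs@atoms$z - ctr[3])^2)
  expect_gte(sum(g[, , , 2]), sum(d <= 20))
})

test_that("quarter-turn augmentation permutes voxels and cycles with period 4", {
  set.seed(11)
  g <- array(rnorm(9^3 * 22), dim = c(9, 9, 9, 22))
  for (ax in 1:3) {
    r <- g
    for (k in 1:4) r <- augmentRotate90(r, axis = ax)
    expect_identical(r, g)
    r1 <- augmentRotate90(g, axis = ax)
    expect_equal(apply(r1, 4, sum), apply(g, 4, sum))
    expect_false(identical(r1, g))
  }
  # seeded axis choice reproducible
  a <- augmentRotate90(g, seed = 3)
  b <- augmentRotate90(g, seed = 3)
  expect_identical(a, b)
})

test_that("grid datasets stream to disk and read back", {
  toy <- makeToyComplex(toyComplexSpec(receptorResidues = 8, interface = c(2, 5)))
  cloud <- generateSurface(toy$receptor)
  f <- atomFeatures(toy$receptor)
  sp <- balancedSample(cloud, toy$antigen, n = 10, seed = 2)
  dir <- tempfile()
  mf <- writeGridDataset(toy$receptor, cloud, sp, f, dir = dir, size = 9,
                         chunkSize = 8, structureId = "toy")
  expect_equal(nrow(mf), 20)
  gs <- readGridDataset(dir)
  expect_equal(dim(gridArray(gs))[5], 20)
  expect_equal(sum(gridLabels(gs)), 10)
  # identical to the in-memory construction
  gs2 <- buildGridSet(toy$receptor, cloud, sp, f, size = 9, structureId = "toy")
  expect_equal(gridArray(gs), gridArray(gs2))
})
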