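fixtureCloudScores <- function(nPoints = 40, nRes = 6, seed = 3) {
  set.seed(seed)
  resIdx <- sample(nRes, nPoints, replace = TRUE)
  parentRes <- data.frame(chain = "H", resno = resIdx, icode = "",
                          resname = "GLY", stringsAsFactors = FALSE)
  cloud <- makeCloud(matrix(rnorm(nPoints * 3), ncol = 3),
                     matrix(rep(c(0, 0, 1), nPoints), ncol = 3, byrow = TRUE),
                     parentRes)
  toy <- makeToyComplex(toyComplexSpec(receptorResidues = nRes, interface = 2))
  list(receptor = toy$receptor, cloud = cloud,
       scores = runif(nPoints), resIdx = resIdx)
}

test_that("residue scores are the max over surface-point scores", {
  fx <- fixtureCloudScores()
  p <- aggregateResidueScores(fx$receptor, fx$cloud, fx$scores)
  rs <- residueScores(p)
  # independent group-by-max oracle
  oracle <- tapply(fx$scores, fx$resIdx, max)
  got <- rs$score[match(as.integer(names(oracle)), rs$resno)]
  expect_equal(got, as.numeric(oracle))
  # explicit examples: max of {0.2, 0.9, 0.4} and a single-point residue
  cloud3 <- makeCloud(matrix(0, 4, 3),
                      matrix(rep(c(0, 0, 1), 4), ncol = 3, byrow = TRUE),
                      data.frame(chain = "H", resno = c(1, 1, 1, 2),
                                 icode = "", resname = "GLY",
                                 stringsAsFactors = FALSE))
  toy2 <- makeToyComplex(toyComplexSpec(receptorResidues = 2, interface = 1))
  p3 <- aggregateResidueScores(toy2$receptor, cloud3, c(0.2, 0.9, 0.4, 0.37))
  expect_equal(residueScores(p3)$score, c(0.9, 0.37))
})

test_that("aggregation is permutation-invariant and monotone", {
  fx <- fixtureCloudScores(seed = 5)
  p0 <- aggregateResidueScores(fx$receptor, fx$cloud, fx$scores)
  set.seed(6)
  perm <- sample(length(fx$scores))
  cloudP <- makeCloud(fx$cloud@points[perm, ], fx$cloud@normals[perm, ],
                      fx$cloud@parentRes[perm, ])
  pP <- aggregateResidueScores(fx$receptor, cloudP, fx$scores[perm])
  expect_equal(residueScores(p0)$score, residueScores(pP)$score)
  # raising one point score never lowers any residue score
  s2 <- fx$scores
  s2[10] <- min(1, s2[10] + 0.3)
  p2 <- aggregateResidueScores(fx$receptor, fx$cloud, s2)
  expect_true(all(residueScores(p2)$score >= residueScores(p0)$score))
  expect_true(all(residueScores(p0)$score >= 0 & residueScores(p0)$score <= 1))
})

test_that("buried residues get score zero and a flag", {
  # cloud touching only residues 1-2 of a 4-residue receptor
  toy <- makeToyComplex(toyComplexSpec(receptorResidues = 4, interface = 1))
  cloud <- makeCloud(matrix(0, 3, 3),
                     matrix(rep(c(0, 0, 1), 3), ncol = 3, byrow = TRUE),
                     data.frame(chain = "H", resno = c(1, 1, 2), icode = "",
                                resname = "GLY", stringsAsFactors = FALSE))
  p <- aggregateResidueScores(toy$receptor, cloud, c(0.3, 0.6, 0.8))
  rs <- residueScores(p)
  expect_equal(rs$score, c(0.6, 0.8, 0, 0))
  expect_equal(rs$noSurface, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("classification uses strict exceedance at both thresholds", {
  toy <- makeToyComplex(toyComplexSpec(receptorResidues = 3, interface = 1))
  cloud <- makeCloud(matrix(0, 3, 3),
                     matrix(rep(c(0, 0, 1), 3), ncol = 3, byrow = TRUE),
                     data.frame(chain = "H", resno = 1:3, icode = "",
                                resname = "GLY", stringsAsFactors = FALSE))
  p <- aggregateResidueScores(toy$receptor, cloud, c(0.51, 0.50, 0.70))
  cls <- classifyResidues(p, 0.5)
  expect_equal(unname(cls), c(TRUE, FALSE, TRUE))   # 0.50 is NOT binding
  cls734 <- classifyResidues(p, 0.734)
  expect_equal(unname(cls734), c(FALSE, FALSE, FALSE))
  expect_error(classifyResidues(p, 1.2), "threshold")
})

test_that("annotated PDB broadcasts residue scores into the b-factor column", {
  toy <- makeToyComplex(toyComplexSpec(receptorResidues = 3, interface = 2))
  cloud <- generateSurface(toy$receptor)
  scores <- runif(nrow(surfacePoints(cloud)))
  p <- aggregateResidueScores(toy$receptor, cloud, scores)
  tf <- tempfile(fileext = ".pdb")
  writeBfactorPDB(toy$receptor, p, tf)
  back <- readPDB(tf, role = "receptor")
  rs <- residueScores(p)
  for (i in 1:3) {
    atoms <- atomTable(back)[atomTable(back)$resno == i, ]
    expect_equal(atoms$bfactor, rep(round(rs$score[i], 2), nrow(atoms)))
  }
  expect_equal(atomTable(back)$x, atomTable(toy$receptor)$x, tolerance = 1e-3)
})

test_that("pocket PDB contains one record per point above threshold", {
  fx <- fixtureCloudScores(seed = 9)
  p <- aggregateResidueScores(fx$receptor, fx$cloud, fx$scores)
  tf <- tempfile(fileext = ".pdb")
  writePocketPDB(fx$cloud, p, tf, threshold = 0.6)
  lines <- readLines(tf)
  het <- grep("^HETATM", lines, value = TRUE)
  expect_length(het, sum(fx$scores > 0.6))
  # records parse as PDB
  if (length(het)) {
    parsed <- readPDBText(paste(c(het, "END"), collapse = "\n"),
                          role = "receptor")
    expect_equal(nrow(atomTable(parsed)), length(het))
  }
  # all-zero scores: empty pocket
  p0 <- aggregateResidueScores(fx$receptor, fx$cloud, rep(0, length(fx$scores)))
  writePocketPDB(fx$cloud, p0, tf, threshold = 0.5)
  expect_length(grep("^HETATM", readLines(tf)), 0)
})

test_that("blind inference runs without any antigen and scores all points", {
  toy <- makeToyComplex(toyComplexSpec(receptorResidues = 4, interface = 2))
  cloud <- generateSurface(toy$receptor)
  m <- buildModel(reducedModelConfig(), seed = 3)
  p <- inferParatope(m, toy$receptor, cloud)
  expect_length(pointScores(p), nrow(surfacePoints(cloud)))
  expect_true(all(pointScores(p) >= 0 & pointScores(p) <= 1))
  rs <- residueScores(p)
  expect_equal(nrow(rs), 4)
  # residue score equals max over its points
  for (i in 1:4) {
    pts <- pointScores(p)[cloud@parentRes$resno == i]
    if (length(pts)) expect_equal(rs$score[i], max(pts))
  }
})
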