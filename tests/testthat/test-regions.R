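test_that("IMGT lookup matches the printed ranges at every boundary", {
  expect_equal(regionOf(c(1, 26)), c("FR1", "FR1"))
  expect_equal(regionOf(c(27, 38)), c("CDR1", "CDR1"))
  expect_equal(regionOf(c(39, 55)), c("FR2", "FR2"))
  expect_equal(regionOf(c(56, 65)), c("CDR2", "CDR2"))
  expect_equal(regionOf(c(66, 104)), c("FR3", "FR3"))
  expect_equal(regionOf(c(105, 117)), c("CDR3", "CDR3"))
  expect_equal(regionOf(c(118, 128)), c("FR4", "FR4"))
  expect_equal(regionOf(c(129, 130)), c("constant", "constant"))
  expect_error(regionOf(0), ">= 1")
})

test_that("CDR+-2 extends loops along the ordered chain and truncates at ends", {
  mask <- contiguousMask(130)
  sel <- cdrPlusMinus2(mask)
  m <- regionTable(mask)
  # CDR1 27-38 extends to 25-40
  expect_true(all(sel[m$imgt >= 25 & m$imgt <= 40]))
  expect_false(any(sel[m$imgt %in% c(24, 41, 53)]))
  # CDR3 105-117 -> 103-119
  expect_true(all(sel[m$imgt >= 103 & m$imgt <= 119]))
  expect_false(any(sel[m$imgt %in% c(102, 120)]))
  # superset of CDR
  expect_true(all(sel[grepl("^CDR", m$region)]))
  # loop at chain start: only the available flank
  tiny <- buildRegionMask(data.frame(chain = "H", resno = 1:6,
                                     imgt = c(27, 28, 39, 40, 41, 42),
                                     chainType = "heavy"))
  selT <- cdrPlusMinus2(tiny)
  expect_equal(selT, c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  # flanking works on ordered positions, not numbering arithmetic:
  gap <- buildRegionMask(data.frame(chain = "H", resno = 1:5,
                                    imgt = c(20, 26, 27, 38, 50),
                                    chainType = "heavy"))
  expect_equal(cdrPlusMinus2(gap), c(TRUE, TRUE, TRUE, TRUE, TRUE))
})

test_that("scope sets nest monotonically: CDR in CDR+-2 in Fv in Fab", {
  mask <- contiguousMask(140)
  cdr <- scopeResidues(mask, "CDR")
  pm2 <- scopeResidues(mask, "CDRpm2")
  fv <- scopeResidues(mask, "Fv")
  fab <- scopeResidues(mask, "Fab")
  expect_true(all(pm2[cdr]))
  expect_true(all(fv[pm2]))
  expect_true(all(fab[fv]))
  expect_true(sum(cdr) < sum(pm2) && sum(pm2) < sum(fv) && sum(fv) < sum(fab))
  # per-loop scopes select by chain type
  expect_equal(sum(scopeResidues(mask, "CDRH3")), 13)
  expect_equal(sum(scopeResidues(mask, "CDRL3")), 0)
})

test_that("mask validation rejects malformed mappings", {
  expect_error(buildRegionMask(data.frame(chain = "H", resno = 1:3,
                                          imgt = c(5, 3, 4),
                                          chainType = "heavy")),
               "non-decreasing")
  expect_error(buildRegionMask(data.frame(chain = "H", resno = 1,
                                          imgt = 0, chainType = "heavy")))
  expect_error(buildRegionMask(data.frame(chain = "H", resno = 1,
                                          imgt = 5, chainType = "kappa")))
})

test_that("ranking metrics agree with brute-force oracles, ties included", {
  # perfect separation
  r <- evaluateRegions(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc_roc, 1.0)
  expect_equal(r$auc_pr, 1.0)
  # hand-counted concordance: pos {0.9, 0.3}, neg {0.8, 0.2} -> 3/4 pairs
  expect_equal(aurocScore(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(aurocOracle(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  # randomized fixtures with heavy ties
  for (seed in 1:8) {
    set.seed(seed)
    n <- 20
    scores <- round(runif(n), 1)   # forces ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(aurocScore(scores, labels), aurocOracle(scores, labels))
    expect_equal(auprScore(scores, labels), auprOracle(scores, labels))
  }
})

test_that("MCC vanishes for label-independent predictions", {
  set.seed(123)
  n <- 1e4
  r <- evaluateRegions(runif(n), rbinom(n, 1, 0.5), threshold = 0.5)
  expect_lt(abs(r$mcc), 0.03)
})

test_that("CAUROC is the median per-complex AUROC, skipping one-class cases", {
  set.seed(7)
  scores <- c(); labels <- c(); cid <- c()
  perComplex <- numeric(7)
  for (k in 1:7) {
    n <- 12
    s <- runif(n); l <- rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2) l[1] <- 1 - l[1]
    perComplex[k] <- aurocOracle(s, l)
    scores <- c(scores, s); labels <- c(labels, l); cid <- c(cid, rep(k, n))
  }
  r <- evaluateRegions(scores, labels, complexId = cid)
  expect_equal(r$cauroc, median(perComplex))
  # adding a single-class complex leaves the median over the valid ones
  scores2 <- c(scores, runif(5)); labels2 <- c(labels, rep(1, 5))
  cid2 <- c(cid, rep(8, 5))
  expect_warning(r2 <- evaluateRegions(scores2, labels2, complexId = cid2),
                 "single-class")
  expect_equal(r2$cauroc, median(perComplex))
})

test_that("Fab metrics restricted to Fv equal direct Fv metrics", {
  mask <- contiguousMask(140)
  set.seed(31)
  n <- 140
  scores <- runif(n)
  labels <- rbinom(n, 1, 0.3)
  fv <- scopeResidues(mask, "Fv")
  direct <- evaluateRegions(scores, labels, mask, scope = "Fv")
  restricted <- evaluateRegions(scores[fv], labels[fv])
  for (f in c("auc_roc", "auc_pr", "f1", "mcc", "accuracy", "precision",
              "recall", "npv", "spc", "fpr"))
    expect_equal(direct[[f]], restricted[[f]], info = f)
})

test_that("single-class scopes report missing AUROC and thresholds validate", {
  r <- evaluateRegions(c(0.2, 0.9), c(1, 1))
  expect_true(is.na(r$auc_roc))
  expect_error(evaluateRegions(0.5, 1, threshold = 2), "threshold")
})

test_that("positional baseline recovers binding proportions", {
  mkComplex <- function(labels) {
    n <- length(labels)
    mask <- contiguousMask(n)
    lab <- new("BindingLabels",
               labels = data.frame(chain = "H", resno = 1:n, icode = "",
                                   resname = "GLY", binding = labels,
                                   stringsAsFactors = FALSE), cutoff = 4.5)
    list(mask = mask, labels = lab)
  }
  train <- list(mkComplex(c(TRUE, FALSE, TRUE)), mkComplex(c(TRUE, FALSE, FALSE)),
                mkComplex(c(TRUE, TRUE, FALSE)), mkComplex(c(FALSE, FALSE, FALSE)))
  bl <- positionalBaseline(train)
  test <- contiguousMask(4)
  sc <- predictBaseline(bl, test)
  # positions bind in 3/4, 1/4 and 1/4 of the cohort; position 4 never seen
  expect_equal(sc, c(3 / 4, 1 / 4, 1 / 4, 0))
  expect_error(positionalBaseline(list()), "empty")
})
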