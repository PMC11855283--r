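# Fixtures and independent oracles shared across the suite.

# brute-force all-pairs residue labelling oracle (O(n*m) double loop)
bruteForceLabels <- function(receptor, antigen, cutoff = 4.5) {
  ra <- atomTable(receptor, heavyOnly = TRUE)
  ag <- atomTable(antigen, heavyOnly = TRUE)
  res <- residueKeys(receptor)
  out <- logical(nrow(res))
  for (i in seq_len(nrow(res))) {
    sub <- ra[ra$chain == res$chain[i] & ra$resno == res$resno[i] &
                ra$icode == res$icode[i], , drop = FALSE]
    best <- Inf
    for (j in seq_len(nrow(sub)))
      for (k in seq_len(nrow(ag)))
        best <- min(best, sqrt((sub$x[j] - ag$x[k])^2 +
                                 (sub$y[j] - ag$y[k])^2 +
                                 (sub$z[j] - ag$z[k])^2))
    out[i] <- best <= cutoff
  }
  names(out) <- paste(res$chain, res$resno, res$icode, sep = "\r")
  out
}

# random protein-like structure: residues of 1-4 atoms scattered in a box
randomStructure <- function(nAtoms, role = "receptor", box = 25, seed = 1) {
  set.seed(seed)
  resno <- sort(sample(ceiling(nAtoms / 3), nAtoms, replace = TRUE))
  atoms <- data.frame(
    record = "ATOM", serial = seq_len(nAtoms),
    name = paste0("C", seq_len(nAtoms) %% 9), altloc = " ", resname = "GLY",
    chain = "A", resno = resno, icode = "",
    x = runif(nAtoms, 0, box), y = runif(nAtoms, 0, box),
    z = runif(nAtoms, 0, box),
    occupancy = 1, bfactor = 0, element = "C", isHeavy = TRUE,
    stringsAsFactors = FALSE)
  new("AbStructure", atoms = atoms, role = role, cleaned = TRUE)
}

rigidTransform <- function(seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3)
  q <- qr.Q(qr(M))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = rnorm(3, sd = 10))
}

applyRigid <- function(s, tf) {
  xyz <- cbind(s@atoms$x, s@atoms$y, s@atoms$z) %*% t(tf$R)
  xyz <- sweep(xyz, 2, tf$t, "+")
  a <- s@atoms
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  new("AbStructure", atoms = a, role = s@role, cleaned = s@cleaned)
}

# idealised alanine with a real carbonyl for the pattern-flag checks
alaninePDB <- function() {
  paste(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       2.000  -0.750  -1.250  1.00  0.00           C",
    "END", sep = "\n")
}

# three-residue mini-protein plus waters and a sodium ion
dirtyPDB <- function(nProtein = 10, nWater = 2, ion = TRUE) {
  lines <- character(0)
  serial <- 1
  for (i in seq_len(nProtein)) {
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      serial, i, i * 3.8, 0, 0))
    serial <- serial + 1
  }
  for (i in seq_len(nWater)) {
    lines <- c(lines, sprintf(
      "HETATM%5d  O   HOH A%4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
      serial, 900 + i, i * 2.0, 8, 8))
    serial <- serial + 1
  }
  if (ion) {
    lines <- c(lines, sprintf(
      "HETATM%5d NA    NA A 950    %8.3f%8.3f%8.3f  1.00  0.00          NA",
      serial, 5.0, -6.0, 2.0))
  }
  paste(c(lines, "END"), collapse = "\n")
}

# O(n^2) pairwise-concordance AUROC oracle (ties count 1/2)
aurocOracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# threshold-enumeration average-precision oracle
auprOracle <- function(scores, labels) {
  P <- sum(labels == 1)
  if (P == 0 || all(labels == 1)) return(NA_real_)
  th <- sort(unique(scores), decreasing = TRUE)
  lastRec <- 0
  area <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / P
    area <- area + (rec - lastRec) * prec
    lastRec <- rec
  }
  area
}

# small surface cloud from explicit pieces (for aggregation tests)
makeCloud <- function(points, normals, parentRes, parentAtom = seq_len(nrow(points))) {
  new("SurfaceCloud", points = points, normals = normals,
      parentAtom = as.integer(parentAtom), parentRes = parentRes,
      density = 0.5, probe = 1.4)
}

# IMGT mapping for a contiguous heavy chain numbered 1..n
contiguousMask <- function(n = 130, chain = "H", chainType = "heavy") {
  buildRegionMask(data.frame(chain = chain, resno = seq_len(n),
                             imgt = seq_len(n), chainType = chainType,
                             stringsAsFactors = FALSE))
}
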