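# Dot-surface generation. The original pipeline runs the external DMS tool;
# here an equivalent rolling-probe dot surface is built natively (no binary
# dependency) and DMS files can still be ingested for compatibility.

fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Rotation-covariant molecular frame (principal axes with third-moment sign
# convention, third axis by cross product) so that the generated dot surface
# is rigid-equivariant: rotating the structure rotates dots and normals.
canonicalFrame <- function(coords) {
  if (nrow(coords) < 3) return(diag(3))
  X <- sweep(coords, 2, colMeans(coords))
  ev <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)
  Q <- ev$vectors[, 1:2, drop = FALSE]
  for (j in 1:2) {
    p <- X %*% Q[, j]
    s <- sum(p^3)
    if (abs(s) < 1e-12) s <- sum(p * abs(p))
    if (s < 0) Q[, j] <- -Q[, j]
  }
  v3 <- c(Q[2, 1] * Q[3, 2] - Q[3, 1] * Q[2, 2],
          Q[3, 1] * Q[1, 2] - Q[1, 1] * Q[3, 2],
          Q[1, 1] * Q[2, 2] - Q[2, 1] * Q[1, 2])
  cbind(Q, v3, deparse.level = 0)
}

#' Generate a dot-sampled solvent-accessible surface
#'
#' Places a deterministic Fibonacci lattice of dots on each heavy atom's
#' probe-expanded van der Waals sphere (radius r_vdW + probe) at the target
#' density, then removes dots occluded by any neighbouring expanded sphere.
#' Normals point radially outward from the parent atom centre. Dot counts per
#' atom are \code{round(density * 4 pi r^2)}, so the density default of 0.5
#' dots per square Angstrom matches the surface coverage the pipeline was
#' designed around; generation is seed-free and fully reproducible.
#'
#' @param s a cleaned [AbStructure-class] with at least one heavy atom.
#' @param density target dots per square Angstrom (default 0.5).
#' @param probe probe sphere radius in Angstrom (default 1.4, a water probe).
#' @return a [SurfaceCloud-class].
#' @examples
#' toy <- makeToyComplex(toyComplexSpec(receptorResidues = 3, interface = 2))
#' surf <- generateSurface(toy$receptor)
#' surf
#' @export
generateSurface <- function(s, density = 0.5, probe = 1.4) {
  stopifnot_structure(s)
  if (density <= 0) stop("density must be positive")
  a <- s@atoms
  heavyIdx <- which(a$isHeavy)
  centers <- cbind(a$x[heavyIdx], a$y[heavyIdx], a$z[heavyIdx])
  radii <- vdwRadius(a$element[heavyIdx]) + probe
  counts <- pmax(1L, as.integer(round(density * 4 * pi * radii^2)))
  total <- sum(counts)
  pts <- matrix(0, total, 3)
  nrm <- matrix(0, total, 3)
  parent <- integer(total)
  off <- 0L
  Q <- canonicalFrame(centers)
  for (k in seq_along(heavyIdx)) {
    u <- fibonacciSphere(counts[k]) %*% t(Q)
    idx <- off + seq_len(counts[k])
    pts[idx, ] <- sweep(u * radii[k], 2, centers[k, ], "+")
    nrm[idx, ] <- u
    parent[idx] <- k
    off <- off + counts[k]
  }
  occ <- occluded_cpp(pts, parent, centers, radii)
  keep <- !occ
  pa <- heavyIdx[parent[keep]]
  methods::new("SurfaceCloud",
    points = pts[keep, , drop = FALSE],
    normals = nrm[keep, , drop = FALSE],
    parentAtom = as.integer(pa),
    parentRes = data.frame(chain = a$chain[pa], resno = a$resno[pa],
                           icode = a$icode[pa], resname = a$resname[pa],
                           stringsAsFactors = FALSE),
    density = density, probe = probe)
}

#' Read a DMS dot-surface file
#'
#' Parses the whitespace-separated DMS dialect: residue name, residue number
#' (optionally suffixed with a chain letter), atom name, x y z, a point type
#' code, area, and an optional normal triple. Records without a normal triple
#' are surface-free atom records or degenerate points and are dropped with a
#' logged count. Parent atoms are resolved against \code{s}; unresolvable
#' records are an error listing the offenders.
#'
#' @param path path to a DMS file.
#' @param s the [AbStructure-class] the surface belongs to.
#' @return a [SurfaceCloud-class] (density slot is \code{NA}: DMS files do
#'   not record it).
#' @export
readDMS <- function(path, s) {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot_structure(s, needHeavy = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  nt <- lengths(toks)
  isAtomRec <- nt >= 7 & vapply(toks, function(t) substr(t[7], 1, 1) == "A", logical(1))
  hasNormal <- nt >= 11
  dropped <- sum(!hasNormal & !isAtomRec)
  if (dropped > 0)
    message("readDMS: dropped ", dropped, " surface record(s) without normals")
  toks <- toks[hasNormal & !isAtomRec]
  if (!length(toks)) stop("no usable surface records in ", path)
  m <- do.call(rbind, toks)
  resname <- toupper(m[, 1])
  resTok <- m[, 2]
  resno <- as.integer(sub("[^0-9].*$", "", resTok))
  chain <- sub("^[0-9]+", "", resTok)
  aname <- toupper(m[, 3])
  xyz <- matrix(as.numeric(m[, 4:6]), ncol = 3)
  nrm <- matrix(as.numeric(m[, 9:11]), ncol = 3)
  if (anyNA(xyz) || anyNA(nrm) || anyNA(resno))
    stop("malformed numeric fields in DMS file ", path)
  nn <- sqrt(rowSums(nrm^2))
  if (any(nn == 0)) stop("zero-length normal in DMS file ", path)
  nrm <- nrm / nn
  a <- s@atoms
  akey <- paste(toupper(a$resname), a$resno, toupper(a$name), sep = "\r")
  key <- paste(resname, resno, aname, sep = "\r")
  pa <- match(key, akey)
  # honour the chain suffix when present and the chain-free match failed
  hasChain <- nzchar(chain)
  if (any(hasChain)) {
    akeyC <- paste(toupper(a$resname), a$resno, toupper(a$name), a$chain, sep = "\r")
    keyC <- paste(resname, resno, aname, chain, sep = "\r")
    pa[hasChain] <- match(keyC[hasChain], akeyC)
  }
  if (anyNA(pa)) {
    bad <- unique(paste(resname, resTok, aname)[is.na(pa)])
    stop("DMS records do not match the structure: ",
         paste(utils::head(bad, 10), collapse = "; "))
  }
  methods::new("SurfaceCloud",
    points = xyz, normals = nrm, parentAtom = as.integer(pa),
    parentRes = data.frame(chain = a$chain[pa], resno = a$resno[pa],
                           icode = a$icode[pa], resname = a$resname[pa],
                           stringsAsFactors = FALSE),
    density = NA_real_, probe = NA_real_)
}
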