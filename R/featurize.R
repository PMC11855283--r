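# Balanced surface sampling, 22-channel per-atom features, and
# normal-aligned voxel grids.

.channel_names <- c("classB", "classC", "classN", "classO", "classP",
                    "classS", "classSe", "classHalogen", "classMetal",
                    "hybridization", "heavyValence", "heterovalence",
                    "partialCharge", "hydrophobic", "aromatic", "acceptor",
                    "donor", "ring", "amberCharge", "charmmCharge",
                    "amberRadius", "charmmRadius")

# distance-based bond perception between heavy atoms, chunked so large
# structures never materialise a full distance matrix
bondNeighbors <- function(coords, elements, slack = 0.45) {
  n <- nrow(coords)
  rc <- covRadius(elements)
  nb <- vector("list", n)
  maxcut <- 2 * max(rc) + slack
  chunk <- max(1L, as.integer(2e6 / max(1, n)))
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    d2 <- outer(rowSums(coords[s:e, , drop = FALSE]^2), rowSums(coords^2), "+") -
      2 * coords[s:e, , drop = FALSE] %*% t(coords)
    thr <- outer(rc[s:e], rc, "+") + slack
    hit <- d2 <= thr^2 & d2 > 1e-8
    for (i in seq_len(e - s + 1L)) nb[[s + i - 1L]] <- which(hit[i, ])
  }
  nb
}

#' Per-atom feature channels
#'
#' Computes the 22 feature channels for every heavy atom of a structure:
#' nine element-class one-hots (B, C, N, O, P, S, Se, halogen, metal), four
#' atom properties (hybridization coded sp=1/sp2=2/sp3=3, heavy valence,
#' heterovalence, partial charge), five pattern flags (hydrophobic, aromatic,
#' acceptor, donor, ring), and four force-field channels (AMBER/CHARMM charge
#' and radius). Force-field channels come from PQR files when supplied,
#' otherwise from the packaged residue-template tables; atoms missing from a
#' PQR get zeros and the miss count is logged. Channels 1-18 never depend on
#' the force-field source.
#'
#' @param s a cleaned [AbStructure-class].
#' @param pqrAmber,pqrCharmm optional paths to PQR files (one per force
#'   field) carrying per-atom charge and radius.
#' @return numeric matrix (heavy atoms x 22) with an \code{"atomIndex"}
#'   attribute giving each row's index into the full atom table.
#' @export
atomFeatures <- function(s, pqrAmber = NULL, pqrCharmm = NULL) {
  stopifnot_structure(s)
  a <- s@atoms
  hi <- which(a$isHeavy)
  ah <- a[hi, , drop = FALSE]
  el <- toupper(ah$element)
  resname <- toupper(ah$resname)
  name <- toupper(ah$name)
  n <- length(hi)
  f <- matrix(0, n, 22, dimnames = list(NULL, .channel_names))

  cls <- rep(NA_character_, n)
  cls[el == "B"] <- "classB";  cls[el == "C"] <- "classC"
  cls[el == "N"] <- "classN";  cls[el == "O"] <- "classO"
  cls[el == "P"] <- "classP";  cls[el == "S"] <- "classS"
  cls[el == "SE"] <- "classSe"
  cls[el %in% .halogens] <- "classHalogen"
  cls[el %in% .metals] <- "classMetal"
  unclass <- is.na(cls)
  if (any(unclass))
    warning(sum(unclass), " atom(s) with unclassifiable element; ",
            "atom-class channels left all-zero")
  for (i in which(!unclass)) f[i, cls[i]] <- 1

  nb <- bondNeighbors(cbind(ah$x, ah$y, ah$z), el)
  f[, "heavyValence"] <- lengths(nb)
  f[, "heterovalence"] <- vapply(nb, function(j) sum(el[j] != "C"), numeric(1))

  arom <- inNamedList(.aromatic_atoms, resname, name)
  ring <- arom | inNamedList(.ring_extra, resname, name)
  acc <- name %in% c("O", "OXT") | inNamedList(.acceptor_atoms, resname, name)
  don <- (name == "N" & resname != "PRO") | inNamedList(.donor_atoms, resname, name)
  sp2 <- arom | name %in% c("C", "O", "OXT", "N") |
    inNamedList(.sp2_extra, resname, name)
  f[, "aromatic"] <- as.numeric(arom)
  f[, "ring"] <- as.numeric(ring)
  f[, "acceptor"] <- as.numeric(acc)
  f[, "donor"] <- as.numeric(don)
  f[, "hybridization"] <- ifelse(sp2, 2, 3)
  hydroph <- (el == "C" &
                vapply(nb, function(j) all(el[j] %in% c("C", "H")), logical(1))) |
    el %in% .halogens
  f[, "hydrophobic"] <- as.numeric(hydroph)

  internal <- internalFFParams(resname, name, el)
  f[, "partialCharge"] <- internal$amberCharge
  f[, "amberCharge"] <- internal$amberCharge
  f[, "charmmCharge"] <- internal$charmmCharge
  f[, "amberRadius"] <- internal$amberRadius
  f[, "charmmRadius"] <- internal$charmmRadius
  if (!is.null(pqrAmber)) {
    p <- matchPQR(readPQR(pqrAmber), ah, "AMBER")
    f[, "amberCharge"] <- p$charge
    f[, "amberRadius"] <- p$radius
  }
  if (!is.null(pqrCharmm)) {
    p <- matchPQR(readPQR(pqrCharmm), ah, "CHARMM")
    f[, "charmmCharge"] <- p$charge
    f[, "charmmRadius"] <- p$radius
  }
  attr(f, "atomIndex") <- hi
  f
}

#' Read a PQR file
#'
#' PQR is PDB-like with whitespace-separated fields whose last two numeric
#' columns are per-atom partial charge and radius. The chain column is
#' optional, as emitted by common PQR generators.
#'
#' @param path path to a PQR file.
#' @return data.frame with \code{name}, \code{resname}, \code{chain},
#'   \code{resno}, \code{charge}, \code{radius}.
#' @export
readPQR <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("^(ATOM|HETATM)", lines)]
  if (!length(lines)) stop("no ATOM/HETATM records in PQR file ", path)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  parse1 <- function(t) {
    # ATOM serial name resname [chain] resno x y z charge radius
    hasChain <- is.na(suppressWarnings(as.numeric(t[5])))
    off <- if (hasChain) 1L else 0L
    c(name = t[3], resname = t[4], chain = if (hasChain) t[5] else "",
      resno = t[5 + off], charge = t[9 + off], radius = t[10 + off])
  }
  m <- t(vapply(toks, parse1, character(6)))
  data.frame(name = toupper(m[, "name"]), resname = toupper(m[, "resname"]),
             chain = m[, "chain"], resno = as.integer(m[, "resno"]),
             charge = as.numeric(m[, "charge"]),
             radius = as.numeric(m[, "radius"]), stringsAsFactors = FALSE)
}

matchPQR <- function(pqr, atoms, label) {
  key <- paste(toupper(atoms$resname), atoms$resno, toupper(atoms$name), sep = "\r")
  pkey <- paste(pqr$resname, pqr$resno, pqr$name, sep = "\r")
  i <- match(key, pkey)
  miss <- is.na(i)
  if (any(miss))
    message("atomFeatures: ", sum(miss), " atom(s) missing from ", label,
            " PQR; force-field channels set to 0")
  list(charge = ifelse(miss, 0, pqr$charge[i]),
       radius = ifelse(miss, 0, pqr$radius[i]))
}

#' Balanced sampling of binding / non-binding surface points
#'
#' Surface points within \code{cutoff} (\code{<=} 4.5 Angstrom) of any
#' antigen heavy atom are binding-eligible. Up to \code{n} positives are
#' drawn uniformly without replacement, and an equal number of negatives
#' from the remaining points; when fewer than \code{n} positives exist, the
#' negative count is reduced to match, keeping the sample exactly balanced.
#'
#' @param cloud a [SurfaceCloud-class] of the receptor.
#' @param antigen the antigen [AbStructure-class].
#' @param n cap on positives per receptor (default 800).
#' @param cutoff binding distance cutoff in Angstrom (default 4.5).
#' @param seed RNG seed; the draw is deterministic given the seed.
#' @return object of class \code{SampledPoints}: list with integer point
#'   indices \code{positives}, \code{negatives}, plus \code{seed} and
#'   \code{cutoff}.
#' @export
balancedSample <- function(cloud, antigen, n = 800, cutoff = 4.5, seed = 1) {
  if (!methods::is(cloud, "SurfaceCloud")) stop("cloud must be a SurfaceCloud")
  if (nrow(cloud@points) == 0) stop("empty surface cloud")
  ag <- heavyCoords(antigen)
  if (!nrow(ag)) stop("antigen has no heavy atoms")
  isPos <- within_cutoff_cpp(cloud@points, ag, cutoff)
  posIdx <- which(isPos)
  negIdx <- which(!isPos)
  if (!length(posIdx)) {
    warning("no binding-eligible surface points; pair is unusable for training")
    out <- list(positives = integer(0), negatives = integer(0),
                seed = seed, cutoff = cutoff)
    class(out) <- "SampledPoints"
    return(out)
  }
  k <- min(n, length(posIdx))
  k <- min(k, length(negIdx) + 0L)  # degenerate: fewer negatives than positives
  sel <- withSeed(seed, {
    p <- sort(sample(posIdx, k))
    ng <- sort(sample(negIdx, k))
    list(p = p, n = ng)
  })
  out <- list(positives = sel$p, negatives = sel$n, seed = seed, cutoff = cutoff)
  class(out) <- "SampledPoints"
  out
}

#' @export
print.SampledPoints <- function(x, ...) {
  cat(sprintf("SampledPoints: %d positives + %d negatives (seed %d)\n",
              length(x$positives), length(x$negatives), x$seed))
  invisible(x)
}

#' Normal-aligned local frame
#'
#' Builds the orthonormal right-handed 3x3 rotation whose third row is the
#' surface normal; the in-plane tangent is the global x-axis projected into
#' the tangent plane (y-axis when the normal is nearly parallel to x),
#' Gram-Schmidt orthonormalised. Rows transform world offsets into grid
#' coordinates.
#'
#' @param normal numeric length-3 vector of approximately unit norm.
#' @return 3x3 rotation matrix with \code{R[3,] == normal}.
#' @export
localFrame <- function(normal) {
  nn <- sqrt(sum(normal^2))
  if (!is.finite(nn) || nn < 1e-8) stop("zero-norm normal")
  n <- normal / nn
  t0 <- if (abs(n[1]) > 0.9) c(0, 1, 0) else c(1, 0, 0)
  t1 <- t0 - sum(t0 * n) * n
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(n[2] * t1[3] - n[3] * t1[2],
          n[3] * t1[1] - n[1] * t1[3],
          n[1] * t1[2] - n[2] * t1[1])
  rbind(t1, t2, n, deparse.level = 0)
}

#' Voxelize a local neighbourhood around a surface point
#'
#' Maps every heavy atom whose frame-transformed offset falls inside the
#' cubic grid to the containing voxel (half-open intervals; the centre voxel
#' spans [-0.5, 0.5) Angstrom per axis at 1 Angstrom resolution) and sums
#' feature vectors channel-wise when several atoms share a voxel. A 41-voxel
#' grid at 1 Angstrom covers every atom within 20 Angstrom of the centre.
#'
#' @param s the [AbStructure-class] the features were computed from.
#' @param center numeric length-3 surface point.
#' @param frame 3x3 rotation from [localFrame()].
#' @param features per-atom feature matrix from [atomFeatures()].
#' @param size odd voxel count per axis (default 41).
#' @param resolution voxel edge in Angstrom (default 1.0).
#' @return numeric array (size, size, size, channels).
#' @export
voxelize <- function(s, center, frame, features, size = 41, resolution = 1.0) {
  if (size %% 2 != 1) stop("size must be odd")
  if (resolution <= 0) stop("resolution must be positive")
  hi <- attr(features, "atomIndex")
  a <- s@atoms
  offs <- cbind(a$x[hi] - center[1], a$y[hi] - center[2], a$z[hi] - center[3])
  local <- offs %*% t(frame)
  idx <- floor(local / resolution + 0.5)
  h <- (size - 1) / 2
  keep <- which(idx[, 1] >= -h & idx[, 1] <= h &
                idx[, 2] >= -h & idx[, 2] <= h &
                idx[, 3] >= -h & idx[, 3] <= h)
  nchan <- ncol(features)
  gridFlat <- matrix(0, size^3, nchan)
  if (length(keep)) {
    vox <- (idx[keep, 1] + h) + size * (idx[keep, 2] + h) + size^2 * (idx[keep, 3] + h) + 1
    acc <- rowsum(features[keep, , drop = FALSE], group = vox)
    gridFlat[as.integer(rownames(acc)), ] <- acc
  }
  array(gridFlat, dim = c(size, size, size, nchan))
}

#' Build labelled feature grids for sampled surface points
#'
#' One normal-aligned grid per sampled point; positives are labelled 1,
#' negatives 0.
#'
#' @param s the receptor [AbStructure-class].
#' @param cloud its [SurfaceCloud-class].
#' @param sampled a \code{SampledPoints} object from [balancedSample()], or a
#'   plain integer vector of point indices (labels then all \code{NA}-free 0).
#' @param features per-atom features from [atomFeatures()].
#' @param size,resolution grid geometry (defaults 41 voxels, 1 Angstrom).
#' @param structureId identifier recorded in the provenance table.
#' @return a [FeatureGridSet-class].
#' @export
buildGridSet <- function(s, cloud, sampled, features = atomFeatures(s),
                         size = 41, resolution = 1.0, structureId = "structure") {
  if (inherits(sampled, "SampledPoints")) {
    idx <- c(sampled$positives, sampled$negatives)
    labels <- c(rep(1, length(sampled$positives)), rep(0, length(sampled$negatives)))
    seed <- sampled$seed
  } else {
    idx <- as.integer(sampled)
    labels <- rep(0, length(idx))
    seed <- NA_integer_
  }
  if (!length(idx)) stop("no sampled points")
  if (max(idx) > nrow(cloud@points)) stop("point index outside the cloud")
  nchan <- ncol(features)
  grids <- array(0, dim = c(size, size, size, nchan, length(idx)))
  for (k in seq_along(idx)) {
    i <- idx[k]
    fr <- localFrame(cloud@normals[i, ])
    grids[, , , , k] <- voxelize(s, cloud@points[i, ], fr, features,
                                 size = size, resolution = resolution)
  }
  methods::new("FeatureGridSet", grids = grids, labels = labels,
               provenance = data.frame(structureId = structureId,
                                       pointIndex = idx, label = labels,
                                       seed = seed, stringsAsFactors = FALSE),
               resolution = resolution)
}

#' Random quarter-turn augmentation
#'
#' Rotates a grid (or every grid of a set) by 90 degrees about one uniformly
#' chosen axis; labels are untouched. Four successive turns about the same
#' axis restore the original tensor, and per-channel sums are conserved
#' (voxel permutation).
#'
#' @param grid a (size, size, size, channels) array, or a
#'   [FeatureGridSet-class].
#' @param seed RNG seed for the axis choice (one axis per grid).
#' @param axis optional fixed axis 1..3 (overrides the random choice).
#' @return same type as \code{grid}.
#' @export
augmentRotate90 <- function(grid, seed = 1, axis = NULL) {
  if (methods::is(grid, "FeatureGridSet")) {
    n <- dim(grid@grids)[5]
    axes <- if (is.null(axis)) withSeed(seed, sample(1:3, n, replace = TRUE)) else rep(axis, n)
    out <- grid@grids
    for (k in seq_len(n)) out[, , , , k] <- rotateGrid90(grid@grids[, , , , k], axes[k])
    methods::new("FeatureGridSet", grids = out, labels = grid@labels,
                 provenance = grid@provenance, resolution = grid@resolution)
  } else {
    ax <- if (is.null(axis)) withSeed(seed, sample(1:3, 1)) else axis
    rotateGrid90(grid, ax)
  }
}

rotateGrid90 <- function(x, axis) {
  d <- dim(x)
  if (d[1] != d[2] || d[2] != d[3]) stop("grid must be cubic")
  n <- d[1]
  if (axis == 1) {        # rotate (h, w) plane
    y <- aperm(x, c(1, 3, 2, 4))
    y[, , n:1, , drop = FALSE]
  } else if (axis == 2) { # rotate (d, w) plane
    y <- aperm(x, c(3, 2, 1, 4))
    y[, , n:1, , drop = FALSE]
  } else if (axis == 3) { # rotate (d, h) plane
    y <- aperm(x, c(2, 1, 3, 4))
    y[, n:1, , , drop = FALSE]
  } else stop("axis must be 1, 2 or 3")
}

#' Stream a grid dataset to disk
#'
#' Serialises grids in chunks (compressed RDS) alongside a tab-separated
#' manifest recording structure id, point index, label, sampling seed, chunk
#' file and in-chunk slot, so a training run can be reproduced exactly
#' without holding the full tensor set in memory.
#'
#' @inheritParams buildGridSet
#' @param dir output directory (created if needed).
#' @param chunkSize grids per chunk file (default 64).
#' @return the manifest data.frame, invisibly; written as
#'   \code{manifest.tsv} in \code{dir}.
#' @export
writeGridDataset <- function(s, cloud, sampled, features = atomFeatures(s),
                             dir, size = 41, resolution = 1.0,
                             chunkSize = 64, structureId = "structure") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- c(sampled$positives, sampled$negatives)
  labels <- c(rep(1, length(sampled$positives)), rep(0, length(sampled$negatives)))
  if (!length(idx)) stop("no sampled points to write")
  nchunk <- ceiling(length(idx) / chunkSize)
  manifest <- data.frame(structureId = structureId, pointIndex = idx,
                         label = labels, seed = sampled$seed,
                         chunk = NA_character_, slot = NA_integer_,
                         stringsAsFactors = FALSE)
  for (ci in seq_len(nchunk)) {
    lo <- (ci - 1) * chunkSize + 1
    hihi <- min(length(idx), ci * chunkSize)
    sub <- lo:hihi
    grids <- array(0, dim = c(size, size, size, ncol(features), length(sub)))
    for (k in seq_along(sub)) {
      i <- idx[sub[k]]
      fr <- localFrame(cloud@normals[i, ])
      grids[, , , , k] <- voxelize(s, cloud@points[i, ], fr, features,
                                   size = size, resolution = resolution)
    }
    f <- sprintf("grids_%04d.rds", ci)
    saveRDS(list(grids = grids, labels = labels[sub]), file.path(dir, f))
    manifest$chunk[sub] <- f
    manifest$slot[sub] <- seq_along(sub)
  }
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Load a grid dataset written by [writeGridDataset()]
#'
#' @param dir dataset directory containing \code{manifest.tsv}.
#' @return a [FeatureGridSet-class].
#' @export
readGridDataset <- function(dir) {
  mf <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf)) stop("no manifest.tsv in ", dir)
  manifest <- utils::read.delim(mf, stringsAsFactors = FALSE)
  chunks <- unique(manifest$chunk)
  parts <- lapply(chunks, function(f) readRDS(file.path(dir, f)))
  d <- dim(parts[[1]]$grids)
  n <- sum(vapply(parts, function(p) dim(p$grids)[5], numeric(1)))
  grids <- array(0, dim = c(d[1:4], n))
  labels <- numeric(n)
  off <- 0
  for (p in parts) {
    k <- dim(p$grids)[5]
    grids[, , , , off + seq_len(k)] <- p$grids
    labels[off + seq_len(k)] <- p$labels
    off <- off + k
  }
  methods::new("FeatureGridSet", grids = grids, labels = labels,
               provenance = manifest[, c("structureId", "pointIndex", "label", "seed")],
               resolution = 1.0)
}

#' Label surface points by antigen proximity
#'
#' Convenience used for grid labels and evaluation: TRUE where the surface
#' point lies within \code{cutoff} of any antigen heavy atom.
#'
#' @inheritParams balancedSample
#' @return logical vector, one per surface point.
#' @export
surfacePointLabels <- function(cloud, antigen, cutoff = 4.5) {
  ag <- heavyCoords(antigen)
  if (!nrow(ag)) stop("antigen has no heavy atoms")
  as.logical(within_cutoff_cpp(cloud@points, ag, cutoff))
}
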