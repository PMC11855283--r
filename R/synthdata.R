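# Deterministic generators: toy receptor/antigen complexes with an exactly
# known interface, and planted-signal voxel grids standing in for GPU-scale
# training data.

#' Specification of a toy antibody-antigen complex
#'
#' Receptor residues are rigid 4-atom glycine-like units spaced 6 Angstrom
#' apart along x; the antigen is a lattice of atoms beneath them. Each
#' interface residue has its lowest atom placed exactly \code{minDist} above
#' an antigen atom, every other residue sits at \code{decoySep}, so the
#' binding labels produced by [labelBindingResidues()] equal the interface
#' set exactly whenever \code{minDist <= cutoff < decoySep}.
#'
#' @param receptorResidues residue count of the receptor.
#' @param interface integer indices (1-based) of interface residues.
#' @param minDist interface contact distance in Angstrom (default 3.5).
#' @param decoySep separation of non-interface residues (default 12; must
#'   exceed the labelling cutoff).
#' @param antigenResidues antigen residue count (4 atoms each); default wide
#'   enough to cover the receptor.
#' @param chain receptor chain identifier.
#' @param seed recorded for provenance (the construction is deterministic).
#' @return a \code{ToyComplexSpec} list.
#' @export
toyComplexSpec <- function(receptorResidues = 10, interface = integer(0),
                           minDist = 3.5, decoySep = 12,
                           antigenResidues = NULL, chain = "H", seed = 1) {
  if (any(interface < 1 | interface > receptorResidues))
    stop("interface indices outside the receptor")
  if (decoySep <= 4.5)
    stop("decoySep must exceed the 4.5 Angstrom labelling cutoff")
  if (minDist >= decoySep) stop("minDist must be below decoySep")
  spec <- list(receptorResidues = receptorResidues,
               interface = sort(unique(as.integer(interface))),
               minDist = minDist, decoySep = decoySep,
               antigenResidues = antigenResidues, chain = chain, seed = seed)
  class(spec) <- "ToyComplexSpec"
  spec
}

# rigid local residue geometry: first atom is the unique lowest one
.toy_local <- matrix(c(0.0, 0.0, 0.0,    # N  (contact atom)
                       1.5, 0.0, 0.4,    # CA
                       0.7, 1.2, 0.6,    # C
                       2.2, 1.0, 0.9),   # O
                     ncol = 3, byrow = TRUE)
.toy_names <- c("N", "CA", "C", "O")
.toy_elements <- c("N", "C", "C", "O")

#' Generate a toy complex with known binding labels
#'
#' @param spec a [toyComplexSpec()].
#' @return list with \code{receptor} and \code{antigen}
#'   ([AbStructure-class], already clean) and \code{expected}
#'   (a [BindingLabels-class] holding the planted truth).
#' @examples
#' toy <- makeToyComplex(toyComplexSpec(receptorResidues = 5, interface = c(2, 4)))
#' all.equal(bindingVector(toy$expected),
#'           bindingVector(labelBindingResidues(toy$receptor, toy$antigen)))
#' @export
makeToyComplex <- function(spec) {
  if (!inherits(spec, "ToyComplexSpec")) stop("spec must be a ToyComplexSpec")
  nr <- spec$receptorResidues
  spacing <- 6
  # antigen lattice along x at z = 0, spacing 2, covering the receptor span
  span <- spacing * (nr - 1)
  nAtoms <- if (is.null(spec$antigenResidues)) (span %/% 2) + 3
            else spec$antigenResidues * 4L
  ax <- 2 * (seq_len(nAtoms) - 1) - 2
  if (max(ax) < span + 2)
    ax <- 2 * (seq_len((span %/% 2) + 3) - 1) - 2  # enforce coverage
  agAtoms <- data.frame(
    record = "ATOM", serial = seq_along(ax), name = "C",
    altloc = " ", resname = "GLY", chain = "A",
    resno = ((seq_along(ax) - 1) %/% 4) + 1L, icode = "",
    x = ax, y = 0, z = 0, occupancy = 1, bfactor = 0, element = "C",
    isHeavy = TRUE, stringsAsFactors = FALSE)
  antigen <- methods::new("AbStructure", atoms = agAtoms, role = "antigen",
                          cleaned = TRUE)
  hts <- rep(spec$decoySep, nr)
  hts[spec$interface] <- spec$minDist
  recAtoms <- do.call(rbind, lapply(seq_len(nr), function(i) {
    loc <- sweep(.toy_local, 2, c(spacing * (i - 1), 0, hts[i]), "+")
    data.frame(record = "ATOM", serial = (i - 1) * 4L + 1:4,
               name = .toy_names, altloc = " ", resname = "GLY",
               chain = spec$chain, resno = i, icode = "",
               x = loc[, 1], y = loc[, 2], z = loc[, 3],
               occupancy = 1, bfactor = 0, element = .toy_elements,
               isHeavy = TRUE, stringsAsFactors = FALSE)
  }))
  receptor <- methods::new("AbStructure", atoms = recAtoms, role = "receptor",
                           cleaned = TRUE)
  res <- residueKeys(receptor)
  res$binding <- seq_len(nr) %in% spec$interface
  expected <- methods::new("BindingLabels", labels = res, cutoff = 4.5)
  list(receptor = receptor, antigen = antigen, expected = expected,
       spec = spec)
}

#' Specification of a planted-signal grid dataset
#'
#' Grids are white Gaussian noise in every channel; positive grids
#' additionally carry a constant shift spread over the central 3x3x3 block
#' of one signal channel. The per-voxel shift is
#' \code{effect * noise / sqrt(27)}, so the central-region sum separates the
#' classes by \code{effect} standard deviations of its null distribution —
#' a one-feature logistic oracle attains AUROC \code{pnorm(effect/sqrt(2))}
#' in closed form. Grid edge defaults to 9 voxels: the full-scale 41-voxel
#' geometry at 2000 grids would need ~24 GB and is a GPU-scale object; the
#' channel count stays 22.
#'
#' @param n number of grids (>= 2); classes exactly balanced (within 1).
#' @param size grid edge in voxels (odd, default 9).
#' @param channels channel count (default 22).
#' @param signalChannel channel carrying the planted signal.
#' @param effect class separation in null standard deviations of the
#'   central-region sum.
#' @param noise per-voxel noise standard deviation.
#' @param seed RNG seed; the dataset is a pure function of the spec.
#' @return a \code{PlantedGridSpec} list.
#' @export
plantedGridSpec <- function(n = 2000, size = 9, channels = 22,
                            signalChannel = 13, effect = 5, noise = 1,
                            seed = 1) {
  if (n < 2) stop("n must be at least 2")
  if (size %% 2 != 1) stop("size must be odd")
  if (signalChannel < 1 || signalChannel > channels)
    stop("signalChannel outside the channel range")
  if (noise <= 0) stop("noise must be positive")
  spec <- list(n = n, size = size, channels = channels,
               signalChannel = signalChannel, effect = effect, noise = noise,
               seed = seed)
  class(spec) <- "PlantedGridSpec"
  spec
}

#' Generate planted-signal feature grids
#'
#' @param spec a [plantedGridSpec()].
#' @return a [FeatureGridSet-class]; labels balanced within one grid.
#' @export
makePlantedGrids <- function(spec) {
  if (!inherits(spec, "PlantedGridSpec")) stop("spec must be a PlantedGridSpec")
  n <- spec$n; sz <- spec$size; C <- spec$channels
  withSeed(spec$seed, {
    labels <- sample(rep(c(0, 1), length.out = n))
    grids <- array(stats::rnorm(sz^3 * C * n, sd = spec$noise),
                   dim = c(sz, sz, sz, C, n))
    ctr <- (sz + 1) / 2 + (-1:1)
    shift <- spec$effect * spec$noise / sqrt(27)
    for (i in which(labels == 1))
      grids[ctr, ctr, ctr, spec$signalChannel, i] <-
        grids[ctr, ctr, ctr, spec$signalChannel, i] + shift
    methods::new("FeatureGridSet", grids = grids, labels = labels,
                 provenance = data.frame(structureId = "planted",
                                         pointIndex = seq_len(n),
                                         label = labels, seed = spec$seed,
                                         stringsAsFactors = FALSE),
                 resolution = 1.0)
  })
}

#' Central-region sum of the signal channel
#'
#' The sufficient statistic of the planted signal; used as the independent
#' one-feature oracle in tests.
#'
#' @param grids a [FeatureGridSet-class].
#' @param signalChannel the planted channel.
#' @return numeric vector, one sum per grid.
#' @export
centralRegionSum <- function(grids, signalChannel = 13) {
  sz <- dim(grids@grids)[1]
  ctr <- (sz + 1) / 2 + (-1:1)
  apply(grids@grids[ctr, ctr, ctr, signalChannel, , drop = FALSE], 5, sum)
}
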