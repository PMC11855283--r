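#' @import methods
NULL

#' Cleaned atomic model of a receptor (antibody) or antigen
#'
#' Holds one structure as a flat atom table with stable residue identifiers.
#' Residues are keyed on author chain/number/insertion code; the package never
#' renumbers during I/O. Hydrogens are retained but flagged non-heavy so that
#' every distance computation can restrict itself to heavy atoms.
#'
#' @slot atoms data.frame with one row per atom: \code{record}, \code{serial},
#'   \code{name}, \code{altloc}, \code{resname}, \code{chain}, \code{resno},
#'   \code{icode}, \code{x}, \code{y}, \code{z}, \code{occupancy},
#'   \code{bfactor}, \code{element}, \code{isHeavy}.
#' @slot role either \code{"receptor"} or \code{"antigen"}.
#' @slot cleaned logical; \code{TRUE} once waters/ions/ligands were removed.
#'
#' @seealso [readPDB()], [cleanStructure()], [labelBindingResidues()]
#' @export
setClass("AbStructure",
  representation(atoms = "data.frame", role = "character", cleaned = "logical"),
  prototype(role = "receptor", cleaned = FALSE)
)

setValidity("AbStructure", function(object) {
  a <- object@atoms
  need <- c("record", "serial", "name", "altloc", "resname", "chain", "resno",
            "icode", "x", "y", "z", "occupancy", "bfactor", "element", "isHeavy")
  if (!all(need %in% names(a)))
    return(paste("atoms is missing columns:", paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a) > 0 && !all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("atom coordinates must be finite")
  if (!object@role %in% c("receptor", "antigen"))
    return("role must be 'receptor' or 'antigen'")
  TRUE
})

#' Per-residue binding labels against an antigen
#'
#' A residue is labelled binding iff the minimum heavy-atom distance from any
#' of its atoms to any antigen heavy atom is less than or equal to the cutoff
#' (4.5 Angstrom by default). One comparison convention (\code{<=}) is used
#' everywhere in the package.
#'
#' @slot labels data.frame: \code{chain}, \code{resno}, \code{icode},
#'   \code{resname}, \code{binding} (logical), in receptor residue order.
#' @slot cutoff numeric distance cutoff in Angstrom.
#' @export
setClass("BindingLabels",
  representation(labels = "data.frame", cutoff = "numeric"),
  prototype(cutoff = 4.5)
)

setValidity("BindingLabels", function(object) {
  need <- c("chain", "resno", "icode", "resname", "binding")
  if (!all(need %in% names(object@labels))) return("labels table malformed")
  if (length(object@cutoff) != 1 || !is.finite(object@cutoff) || object@cutoff <= 0)
    return("cutoff must be a single positive number")
  TRUE
})

#' Dot-sampled solvent-accessible surface
#'
#' Quasi-uniform dots on probe-expanded van der Waals spheres with unit
#' outward normals and a parent atom/residue per dot. Produced either by the
#' built-in rolling-probe generator ([generateSurface()]) or parsed from a DMS
#' dot file ([readDMS()]).
#'
#' @slot points numeric matrix n x 3, Angstrom.
#' @slot normals numeric matrix n x 3, unit outward normals.
#' @slot parentAtom integer index into the source structure's atom table.
#' @slot parentRes data.frame with \code{chain}, \code{resno}, \code{icode},
#'   \code{resname} per dot.
#' @slot density target dot density in dots per square Angstrom.
#' @slot probe probe radius in Angstrom.
#' @export
setClass("SurfaceCloud",
  representation(points = "matrix", normals = "matrix", parentAtom = "integer",
                 parentRes = "data.frame", density = "numeric", probe = "numeric"),
  prototype(density = 0.5, probe = 1.4)
)

setValidity("SurfaceCloud", function(object) {
  n <- nrow(object@points)
  if (ncol(object@points) != 3 || ncol(object@normals) != 3)
    return("points and normals must have 3 columns")
  if (nrow(object@normals) != n || length(object@parentAtom) != n ||
      nrow(object@parentRes) != n)
    return("points, normals and parents must agree in length")
  if (n > 0) {
    nn <- sqrt(rowSums(object@normals^2))
    if (any(abs(nn - 1) > 1e-6)) return("normals must be unit vectors (1e-6)")
  }
  TRUE
})

#' A labelled set of voxel feature grids
#'
#' Each grid is a \code{size^3 x channels} local neighbourhood of one surface
#' point, axes aligned to the point's normal frame, 1 Angstrom voxels by
#' default. The full-scale geometry is 41 x 41 x 41 x 22.
#'
#' @slot grids 5-D numeric array (size, size, size, channels, n).
#' @slot labels numeric vector of 0/1 grid labels.
#' @slot provenance data.frame: \code{structureId}, \code{pointIndex},
#'   \code{label}, and the sampling \code{seed}.
#' @slot resolution voxel edge in Angstrom.
#' @export
setClass("FeatureGridSet",
  representation(grids = "array", labels = "numeric", provenance = "data.frame",
                 resolution = "numeric"),
  prototype(resolution = 1.0)
)

setValidity("FeatureGridSet", function(object) {
  d <- dim(object@grids)
  if (length(d) != 5) return("grids must be a 5-D array (D,H,W,C,N)")
  if (!(d[1] == d[2] && d[2] == d[3])) return("grids must be spatially cubic")
  if (d[5] != length(object@labels)) return("labels must match grid count")
  if (length(object@labels) && !all(object@labels %in% c(0, 1)))
    return("labels must be 0/1")
  TRUE
})

#' Surface-point and residue-level binding scores
#'
#' Residue scores are the maximum over that residue's surface-point scores;
#' residues with no surface dots (fully buried) carry score 0 and a
#' \code{noSurface} flag.
#'
#' @slot pointScores numeric vector in [0,1], one per surface point.
#' @slot residueScores data.frame: \code{chain}, \code{resno}, \code{icode},
#'   \code{resname}, \code{score}, \code{noSurface}.
#' @slot threshold classification threshold used by [classifyResidues()].
#' @export
setClass("PredictionSet",
  representation(pointScores = "numeric", residueScores = "data.frame",
                 threshold = "numeric"),
  prototype(threshold = 0.5)
)

setValidity("PredictionSet", function(object) {
  if (length(object@pointScores) &&
      (min(object@pointScores) < 0 || max(object@pointScores) > 1))
    return("point scores must lie in [0,1]")
  need <- c("chain", "resno", "icode", "resname", "score", "noSurface")
  if (!all(need %in% names(object@residueScores)))
    return("residueScores table malformed")
  TRUE
})

#' IMGT region assignment for antibody residues
#'
#' Maps each residue of a numbered chain to its IMGT position and region:
#' FR1 1-26, CDR1 27-38, FR2 39-55, CDR2 56-65, FR3 66-104, CDR3 105-117,
#' FR4 118-128; positions beyond 128 belong to the constant domain. Fv is the
#' union of FR and CDR positions (1-128); Fab is every residue of the chain
#' pair.
#'
#' @slot map data.frame: \code{chain}, \code{resno}, \code{icode},
#'   \code{imgt}, \code{region}, \code{chainType} ("heavy" or "light").
#' @export
setClass("RegionMask", representation(map = "data.frame"))

setValidity("RegionMask", function(object) {
  m <- object@map
  need <- c("chain", "resno", "icode", "imgt", "region", "chainType")
  if (!all(need %in% names(m))) return("map table malformed")
  if (nrow(m)) {
    if (any(m$imgt < 1)) return("IMGT positions must be >= 1")
    if (!all(m$chainType %in% c("heavy", "light")))
      return("chainType must be 'heavy' or 'light'")
    bad <- vapply(split(m$imgt, m$chain), function(p) any(diff(p) < 0), logical(1))
    if (any(bad)) return("IMGT positions must be non-decreasing within a chain")
  }
  TRUE
})
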