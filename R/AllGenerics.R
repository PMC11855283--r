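#' Accessors for the package's core classes
#'
#' Small accessor generics in the Bioconductor style: code outside the
#' package should never reach into slots directly.
#'
#' @param x one of the package's S4 objects.
#' @param ... unused.
#' @return see the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atomTable", function(x, ...) standardGeneric("atomTable"))

#' @rdname accessors
#' @export
setGeneric("residueKeys", function(x, ...) standardGeneric("residueKeys"))

#' @rdname accessors
#' @export
setGeneric("structureRole", function(x) standardGeneric("structureRole"))

#' @rdname accessors
#' @export
setGeneric("surfacePoints", function(x) standardGeneric("surfacePoints"))

#' @rdname accessors
#' @export
setGeneric("surfaceNormals", function(x) standardGeneric("surfaceNormals"))

#' @rdname accessors
#' @export
setGeneric("bindingVector", function(x) standardGeneric("bindingVector"))

#' @rdname accessors
#' @export
setGeneric("gridArray", function(x) standardGeneric("gridArray"))

#' @rdname accessors
#' @export
setGeneric("gridLabels", function(x) standardGeneric("gridLabels"))

#' @rdname accessors
#' @export
setGeneric("pointScores", function(x) standardGeneric("pointScores"))

#' @rdname accessors
#' @export
setGeneric("residueScores", function(x) standardGeneric("residueScores"))

#' @rdname accessors
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))

#' @describeIn accessors the atom data.frame of an [AbStructure-class].
setMethod("atomTable", "AbStructure", function(x, heavyOnly = FALSE, ...) {
  a <- x@atoms
  if (heavyOnly) a[a$isHeavy, , drop = FALSE] else a
})

#' @describeIn accessors unique residues of a structure, in atom order.
setMethod("residueKeys", "AbStructure", function(x, ...) {
  a <- x@atoms
  key <- paste(a$chain, a$resno, a$icode, sep = "\r")
  keep <- !duplicated(key)
  data.frame(chain = a$chain[keep], resno = a$resno[keep], icode = a$icode[keep],
             resname = a$resname[keep], stringsAsFactors = FALSE)
})

#' @describeIn accessors the declared role ("receptor"/"antigen").
setMethod("structureRole", "AbStructure", function(x) x@role)

#' @describeIn accessors n x 3 matrix of surface dot coordinates.
setMethod("surfacePoints", "SurfaceCloud", function(x) x@points)

#' @describeIn accessors n x 3 matrix of unit outward normals.
setMethod("surfaceNormals", "SurfaceCloud", function(x) x@normals)

#' @describeIn accessors named logical vector of residue binding labels.
setMethod("bindingVector", "BindingLabels", function(x) {
  stats::setNames(x@labels$binding,
                  paste(x@labels$chain, x@labels$resno, x@labels$icode, sep = "\r"))
})

#' @describeIn accessors the (D,H,W,C,N) grid array.
setMethod("gridArray", "FeatureGridSet", function(x) x@grids)

#' @describeIn accessors numeric 0/1 labels, one per grid.
setMethod("gridLabels", "FeatureGridSet", function(x) x@labels)

#' @describeIn accessors numeric per-surface-point scores.
setMethod("pointScores", "PredictionSet", function(x) x@pointScores)

#' @describeIn accessors per-residue score table.
setMethod("residueScores", "PredictionSet", function(x) x@residueScores)

#' @describeIn accessors the residue-to-IMGT mapping table.
setMethod("regionTable", "RegionMask", function(x) x@map)

setMethod("show", "AbStructure", function(object) {
  a <- object@atoms
  cat(sprintf("AbStructure (%s%s): %d atoms (%d heavy), %d residues, %d chain(s)\n",
              object@role, if (object@cleaned) ", cleaned" else "",
              nrow(a), sum(a$isHeavy), nrow(residueKeys(object)),
              length(unique(a$chain))))
})

setMethod("show", "BindingLabels", function(object) {
  cat(sprintf("BindingLabels: %d residues, %d binding (cutoff %.2f A)\n",
              nrow(object@labels), sum(object@labels$binding), object@cutoff))
})

setMethod("show", "SurfaceCloud", function(object) {
  cat(sprintf("SurfaceCloud: %d dots (density %.2f /A^2, probe %.2f A)\n",
              nrow(object@points), object@density, object@probe))
})

setMethod("show", "FeatureGridSet", function(object) {
  d <- dim(object@grids)
  cat(sprintf("FeatureGridSet: %d grids of %dx%dx%dx%d (%.1f A voxels), %d positive\n",
              d[5], d[1], d[2], d[3], d[4], object@resolution, sum(object@labels == 1)))
})

setMethod("show", "PredictionSet", function(object) {
  rs <- object@residueScores
  cat(sprintf("PredictionSet: %d surface points, %d residues (%d above %.3f)\n",
              length(object@pointScores), nrow(rs),
              sum(rs$score > object@threshold), object@threshold))
})

setMethod("show", "RegionMask", function(object) {
  m <- object@map
  cat(sprintf("RegionMask: %d residues over %d chain(s); CDR %d, FR %d, constant %d\n",
              nrow(m), length(unique(m$chain)),
              sum(grepl("^CDR", m$region)), sum(grepl("^FR", m$region)),
              sum(m$region == "constant")))
})
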