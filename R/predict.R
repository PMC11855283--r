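#' Blind paratope inference on a receptor
#'
#' Scores every surface point of the receptor with the model and aggregates
#' to residues by taking, for each residue, the maximum over its surface
#' point scores. The signature consumes no antigen: inference is
#' antigen-agnostic by construction. Residues without any surface dot
#' (fully buried) get score 0 and a \code{noSurface} flag.
#'
#' @param model a trained (or untrained) \code{BindingModel}.
#' @param receptor the cleaned receptor [AbStructure-class].
#' @param cloud the receptor's [SurfaceCloud-class].
#' @param features optional per-atom features (recomputed when omitted).
#' @param batchSize evaluation batch size.
#' @param threshold default classification threshold stored on the result.
#' @return a [PredictionSet-class].
#' @export
inferParatope <- function(model, receptor, cloud, features = NULL,
                          batchSize = 32, threshold = 0.5) {
  stopifnot_structure(receptor, what = "receptor")
  if (nrow(cloud@points) == 0) stop("empty surface cloud")
  if (max(cloud@parentAtom) > nrow(receptor@atoms))
    stop("surface cloud does not match the receptor structure")
  if (is.null(features)) features <- atomFeatures(receptor)
  size <- model$cfg$gridSize
  n <- nrow(cloud@points)
  scores <- numeric(n)
  for (s in seq(1, n, by = batchSize)) {
    e <- min(n, s + batchSize - 1)
    batch <- array(0, dim = c(size, size, size, model$cfg$inChannels, e - s + 1))
    for (k in s:e) {
      fr <- localFrame(cloud@normals[k, ])
      batch[, , , , k - s + 1] <- voxelize(receptor, cloud@points[k, ], fr,
                                           features, size = size)
    }
    scores[s:e] <- predictScores(model, batch, batchSize = batchSize)
  }
  aggregateResidueScores(receptor, cloud, scores, threshold = threshold)
}

#' Aggregate surface-point scores to residues
#'
#' The residue score is the maximum of its surface-point scores; this is
#' permutation-invariant and monotone in every point score.
#'
#' @param receptor the receptor [AbStructure-class].
#' @param cloud its [SurfaceCloud-class].
#' @param scores numeric point scores in [0, 1], one per dot.
#' @param threshold default threshold stored on the result.
#' @return a [PredictionSet-class].
#' @export
aggregateResidueScores <- function(receptor, cloud, scores, threshold = 0.5) {
  if (length(scores) != nrow(cloud@points))
    stop("one score per surface point required")
  if (length(scores) && (min(scores) < 0 || max(scores) > 1))
    stop("point scores must lie in [0, 1]")
  res <- residueKeys(receptor)
  rkey <- resKey(res$chain, res$resno, res$icode)
  pkey <- resKey(cloud@parentRes$chain, cloud@parentRes$resno,
                 cloud@parentRes$icode)
  mx <- tapply(scores, factor(pkey, levels = rkey), max)
  res$score <- as.numeric(mx[rkey])
  res$noSurface <- is.na(res$score)
  res$score[res$noSurface] <- 0
  methods::new("PredictionSet", pointScores = as.numeric(scores),
               residueScores = res, threshold = threshold)
}

#' Classify residues at a threshold
#'
#' A residue is predicted binding iff its score strictly exceeds the
#' threshold ("exceeds": ties at the threshold are non-binding). The 0.734
#' threshold is selectable for comparison with sequence-based work; 0.5 is
#' the common default.
#'
#' @param p a [PredictionSet-class].
#' @param threshold numeric in [0, 1].
#' @return named logical vector, one entry per residue.
#' @export
classifyResidues <- function(p, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  rs <- p@residueScores
  stats::setNames(rs$score > threshold, resKey(rs$chain, rs$resno, rs$icode))
}

#' Write prediction-annotated PDB
#'
#' Emits the receptor with every atom's b-factor replaced by its residue's
#' score (fixed-width, 2 decimals); coordinates and all other columns are
#' untouched.
#'
#' @param receptor the receptor [AbStructure-class].
#' @param p a [PredictionSet-class] computed for it.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeBfactorPDB <- function(receptor, p, path) {
  a <- receptor@atoms
  rs <- p@residueScores
  i <- match(resKey(a$chain, a$resno, a$icode),
             resKey(rs$chain, rs$resno, rs$icode))
  if (anyNA(i)) stop("prediction does not cover every receptor residue")
  writePDB(receptor, path, bfactor = rs$score[i])
}

#' Write a pocket PDB of predicted binding surface points
#'
#' One HETATM pseudo-atom per surface point whose score strictly exceeds the
#' threshold.
#'
#' @param cloud the [SurfaceCloud-class].
#' @param p the [PredictionSet-class].
#' @param path output path.
#' @param threshold selection threshold (default: the prediction's).
#' @return the path, invisibly.
#' @export
writePocketPDB <- function(cloud, p, path, threshold = p@threshold) {
  sel <- which(p@pointScores > threshold)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(sel)) {
    lines <- sprintf(paste0("HETATM%5d  O   PKT P%4d    %8.3f%8.3f%8.3f",
                            "%6.2f%6.2f           O"),
                     seq_along(sel) %% 100000L, seq_along(sel) %% 10000L,
                     cloud@points[sel, 1], cloud@points[sel, 2],
                     cloud@points[sel, 3], 1.0, p@pointScores[sel])
    writeLines(lines, con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write the per-residue score table
#'
#' Tab-separated: chain, number, insertion code, residue name, score, and
#' the known binding label when supplied.
#'
#' @param p a [PredictionSet-class].
#' @param path output path.
#' @param labels optional [BindingLabels-class] adding a label column.
#' @return the table, invisibly.
#' @export
writeScoreTable <- function(p, path, labels = NULL) {
  rs <- p@residueScores
  out <- rs[, c("chain", "resno", "icode", "resname", "score")]
  if (!is.null(labels)) {
    lv <- bindingVector(labels)
    out$label <- as.integer(lv[resKey(rs$chain, rs$resno, rs$icode)])
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out)
}
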