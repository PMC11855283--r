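# IMGT region masks, region-scoped evaluation and the positional baseline.

.imgt_breaks <- c(FR1 = 26, CDR1 = 38, FR2 = 55, CDR2 = 65, FR3 = 104,
                  CDR3 = 117, FR4 = 128)

#' IMGT region of a position
#'
#' Deterministic lookup against the IMGT variable-domain ranges: FR1 1-26,
#' CDR1 27-38, FR2 39-55, CDR2 56-65, FR3 66-104, CDR3 105-117, FR4 118-128;
#' anything above 128 is the constant domain.
#'
#' @param imgtPosition integer vector of IMGT positions (>= 1).
#' @return character vector of region labels.
#' @examples
#' regionOf(c(26, 27, 105, 130))
#' @export
regionOf <- function(imgtPosition) {
  if (any(imgtPosition < 1)) stop("IMGT positions must be >= 1")
  labs <- c(names(.imgt_breaks), "constant")
  labs[findInterval(imgtPosition, c(.imgt_breaks + 1L))+ 1L]
}

#' Build a region mask from an IMGT mapping table
#'
#' IMGT positions are an input (the package ships no numbering engine): a
#' mapping table per chain gives author residue number + insertion code and
#' the IMGT position. Positions must be >= 1 and non-decreasing within a
#' chain; the region is derived via [regionOf()].
#'
#' @param mapping data.frame with columns \code{chain}, \code{resno},
#'   \code{icode} (optional, default ""), \code{imgt}, \code{chainType}
#'   ("heavy"/"light").
#' @return a [RegionMask-class].
#' @export
buildRegionMask <- function(mapping) {
  if (!all(c("chain", "resno", "imgt", "chainType") %in% names(mapping)))
    stop("mapping needs chain, resno, imgt, chainType columns")
  if (is.null(mapping$icode)) mapping$icode <- ""
  m <- data.frame(chain = as.character(mapping$chain),
                  resno = as.integer(mapping$resno),
                  icode = as.character(mapping$icode),
                  imgt = as.integer(mapping$imgt),
                  region = regionOf(mapping$imgt),
                  chainType = as.character(mapping$chainType),
                  stringsAsFactors = FALSE)
  methods::new("RegionMask", map = m)
}

#' Read an IMGT mapping table
#'
#' Tab-separated with columns chain, resno, icode, imgt, chainType.
#'
#' @param path file path.
#' @return a [RegionMask-class].
#' @export
readRegionMask <- function(path) {
  buildRegionMask(utils::read.delim(path, stringsAsFactors = FALSE,
                                    colClasses = c(icode = "character")))
}

#' Residues in scope
#'
#' Scope sets nest: CDR is a subset of CDR+-2, which is a subset of Fv
#' (IMGT 1-128), which is a subset of Fab (all residues). CDR+-2 extends
#' each CDR loop by its two sequence-adjacent residues on either side, taken
#' along the ordered chain (robust to insertion-code numbering gaps) and
#' truncated at chain ends.
#'
#' @param mask a [RegionMask-class].
#' @param scope one of \code{"CDR"}, \code{"CDRpm2"}, \code{"Fv"},
#'   \code{"Fab"}, or a single region label (\code{"FR1"}..\code{"FR4"},
#'   \code{"CDR1"}..\code{"CDR3"}) optionally prefixed by chain type as in
#'   \code{"CDRH3"} / \code{"CDRL1"}.
#' @return logical vector over the mask's rows.
#' @export
scopeResidues <- function(mask, scope = c("Fab", "Fv", "CDRpm2", "CDR",
                                          "FR1", "CDR1", "FR2", "CDR2", "FR3",
                                          "CDR3", "FR4", "FR",
                                          "CDRH1", "CDRH2", "CDRH3",
                                          "CDRL1", "CDRL2", "CDRL3")) {
  scope <- match.arg(scope)
  m <- mask@map
  isCDR <- grepl("^CDR", m$region)
  switch(scope,
    Fab = rep(TRUE, nrow(m)),
    Fv = m$imgt <= 128,
    CDR = isCDR,
    CDRpm2 = cdrPlusMinus2(mask),
    FR = grepl("^FR", m$region) & m$imgt <= 128,
    CDRH1 = m$region == "CDR1" & m$chainType == "heavy",
    CDRH2 = m$region == "CDR2" & m$chainType == "heavy",
    CDRH3 = m$region == "CDR3" & m$chainType == "heavy",
    CDRL1 = m$region == "CDR1" & m$chainType == "light",
    CDRL2 = m$region == "CDR2" & m$chainType == "light",
    CDRL3 = m$region == "CDR3" & m$chainType == "light",
    m$region == scope
  )
}

#' CDR loops extended by two flanking residues
#'
#' @param mask a [RegionMask-class].
#' @return logical vector marking every CDR residue plus the two
#'   sequence-adjacent residues at each loop end (by position in the ordered
#'   chain, not numbering arithmetic).
#' @export
cdrPlusMinus2 <- function(mask) {
  m <- mask@map
  out <- logical(nrow(m))
  for (ch in unique(m$chain)) {
    rows <- which(m$chain == ch)
    cdr <- grepl("^CDR", m$region[rows])
    r <- rle(cdr)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    sel <- cdr
    for (k in which(r$values)) {
      lo <- max(1, starts[k] - 2)
      hi <- min(length(rows), ends[k] + 2)
      sel[lo:hi] <- TRUE
    }
    out[rows] <- sel
  }
  out
}

# ---- metrics ------------------------------------------------------------

#' Threshold-free ranking metrics
#'
#' \code{aurocScore} is the Mann-Whitney statistic (ties counted 1/2), equal
#' to the concordance over all (positive, negative) pairs. \code{auprScore}
#' is the step-interpolated area under the precision-recall curve (average
#' precision): precision is averaged at each distinct recall step, which is
#' the convention sequence- and structure-based binding-site work reports.
#'
#' @param scores numeric scores.
#' @param labels 0/1 (or logical) labels.
#' @return numeric scalar; \code{NA} when one class is absent.
#' @export
aurocScore <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname aurocScore
#' @export
auprScore <- function(scores, labels) {
  labels <- as.numeric(labels)
  P <- sum(labels == 1)
  if (P == 0 || all(labels == 1)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE)  # group ties: evaluate at group ends
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / P
  dRec <- diff(c(0, rec))
  sum(dRec * prec)
}

confusionCounts <- function(scores, labels, threshold) {
  pred <- scores > threshold
  y <- as.logical(labels)
  c(tp = sum(pred & y), fp = sum(pred & !y),
    tn = sum(!pred & !y), fn = sum(!pred & y))
}

#' Region-scoped evaluation of residue predictions
#'
#' Computes the full metric suite on the residues selected by the scope:
#' threshold metrics (accuracy, precision, recall, F1, MCC, NPV, specificity,
#' FPR) at the given threshold (strict \code{>}), threshold-free AUC-ROC and
#' AUC-PR, and CAUROC — the median of per-complex AUROC values, robust to
#' outlier complexes. Complexes whose scoped residues are single-class have
#' undefined AUROC: they are reported as missing, excluded from the CAUROC
#' median with a warning, but still counted in the pooled threshold metrics.
#' Pooled metrics are micro-averaged over residues.
#'
#' @param scores numeric residue scores.
#' @param labels 0/1 or logical residue labels.
#' @param mask a [RegionMask-class] covering the same residues, or NULL to
#'   evaluate everything (Fab behaviour).
#' @param scope see [scopeResidues()].
#' @param threshold classification threshold (0.5 or 0.734 in practice).
#' @param complexId optional factor grouping residues into complexes for
#'   CAUROC.
#' @return a \code{MetricsReport} list.
#' @export
evaluateRegions <- function(scores, labels, mask = NULL, scope = "Fab",
                            threshold = 0.5, complexId = NULL) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  keep <- if (is.null(mask)) rep(TRUE, length(scores))
          else scopeResidues(mask, scope)
  if (length(keep) != length(scores))
    stop("mask does not cover the scored residues")
  s <- scores[keep]; y <- labels[keep]
  cid <- if (is.null(complexId)) NULL else factor(complexId[keep])
  cc <- confusionCounts(s, y, threshold)
  tp <- cc["tp"]; fp <- cc["fp"]; tn <- cc["tn"]; fn <- cc["fn"]
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  prec <- safe(tp, tp + fp)
  rec <- safe(tp, tp + fn)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
        else 2 * prec * rec / (prec + rec)
  mccDen <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mccDen == 0) 0 else (tp * tn - fp * fn) / mccDen
  perComplex <- NULL
  cauroc <- NA_real_
  if (!is.null(cid)) {
    perComplex <- vapply(split(seq_along(s), cid),
                         function(i) aurocScore(s[i], y[i]), numeric(1))
    if (anyNA(perComplex))
      warning(sum(is.na(perComplex)),
              " complex(es) single-class in scope; excluded from CAUROC")
    cauroc <- stats::median(perComplex, na.rm = TRUE)
  }
  out <- list(scope = scope, threshold = threshold, n = length(s),
              nComplexes = if (is.null(cid)) 1L else nlevels(cid),
              auc_roc = aurocScore(s, y), auc_pr = auprScore(s, y),
              cauroc = cauroc, perComplexAUROC = perComplex,
              accuracy = safe(tp + tn, length(s)),
              precision = prec, recall = rec, f1 = f1,
              mcc = as.numeric(mcc),
              npv = safe(tn, tn + fn), spc = safe(tn, tn + fp),
              fpr = safe(fp, fp + tn))
  class(out) <- "MetricsReport"
  out
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf("MetricsReport [%s @ %.3f] n=%d complexes=%d\n", x$scope,
              x$threshold, x$n, x$nComplexes))
  cat(sprintf("  AUC-ROC %.4f  AUC-PR %.4f  CAUROC %s\n", x$auc_roc, x$auc_pr,
              ifelse(is.na(x$cauroc), "NA", sprintf("%.4f", x$cauroc))))
  cat(sprintf("  F1 %.4f  MCC %.4f  Acc %.4f  Prec %.4f  Rec %.4f\n",
              x$f1, x$mcc, x$accuracy, x$precision, x$recall))
  cat(sprintf("  NPV %.4f  SPC %.4f  FPR %.4f\n", x$npv, x$spc, x$fpr))
  invisible(x)
}

#' Write metric reports as JSON lines
#'
#' One JSON object per (scope, threshold) report.
#'
#' @param reports a list of \code{MetricsReport} objects.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMetricsJSONL <- function(reports, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (r in reports) {
    r <- unclass(r)
    r$perComplexAUROC <- NULL
    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, na = "null"), con)
  }
  invisible(path)
}

#' Positional binding-frequency baseline
#'
#' The reference baseline for paratope prediction: the proportion of
#' training residues that bind the antigen at each IMGT sequence position
#' (per chain type) becomes that position's predicted score on test
#' antibodies; positions never seen in training score 0.
#'
#' @param train list of complexes, each a list with elements \code{mask}
#'   (a [RegionMask-class]) and \code{labels} (a [BindingLabels-class]).
#' @return object of class \code{PositionalBaseline}: a function-like table;
#'   apply with [predictBaseline()].
#' @export
positionalBaseline <- function(train) {
  if (!length(train)) stop("empty training set")
  rows <- lapply(train, function(cx) {
    m <- cx$mask@map
    lv <- bindingVector(cx$labels)
    key <- resKey(m$chain, m$resno, m$icode)
    data.frame(chainType = m$chainType, imgt = m$imgt,
               binding = as.numeric(lv[key]), stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows)
  if (anyNA(all$binding))
    stop("every mapped residue needs a binding label")
  agg <- stats::aggregate(binding ~ chainType + imgt, data = all, FUN = mean)
  names(agg)[3] <- "proportion"
  agg$nObs <- stats::aggregate(binding ~ chainType + imgt, data = all,
                               FUN = length)$binding
  out <- list(table = agg)
  class(out) <- "PositionalBaseline"
  out
}

#' @rdname positionalBaseline
#' @param baseline a \code{PositionalBaseline}.
#' @param mask a [RegionMask-class] for the test antibody.
#' @return numeric scores, one per mask row; unseen positions get 0.
#' @export
predictBaseline <- function(baseline, mask) {
  m <- mask@map
  key <- paste(m$chainType, m$imgt)
  bkey <- paste(baseline$table$chainType, baseline$table$imgt)
  i <- match(key, bkey)
  ifelse(is.na(i), 0, baseline$table$proportion[i])
}

#' @export
print.PositionalBaseline <- function(x, ...) {
  cat(sprintf("PositionalBaseline: %d (chainType, position) entries\n",
              nrow(x$table)))
  invisible(x)
}
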