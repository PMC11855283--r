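#' Remove waters, ions and ligands from a structure
#'
#' Strips non-essential components before surface generation and labelling:
#' water residues, monoatomic HETATM ions (fixed name list), and HETATM
#' ligand residues that are neither standard amino acids nor recognised
#' modified residues (MSE and friends are retained as protein). Atom order is
#' otherwise preserved, and the operation is idempotent.
#'
#' @param s an [AbStructure-class].
#' @return the cleaned [AbStructure-class].
#' @export
cleanStructure <- function(s) {
  stopifnot_structure(s, needHeavy = FALSE)
  a <- s@atoms
  if (!nrow(a)) stop("empty structure")
  resname <- toupper(a$resname)
  key <- resKey(a$chain, a$resno, a$icode)
  natoms <- table(key)
  drop <- resname %in% .water_resnames
  isHet <- a$record == "HETATM"
  monoatomic <- as.vector(natoms[key]) == 1L
  drop <- drop | (isHet & monoatomic & resname %in% .ion_resnames)
  keepable <- resname %in% c(.standard_aa, .modified_aa)
  drop <- drop | (isHet & !keepable)
  a <- a[!drop, , drop = FALSE]
  if (!nrow(a)) stop("structure is empty after cleaning (unusable ",
                     s@role, ")")
  rownames(a) <- NULL
  methods::new("AbStructure", atoms = a, role = s@role, cleaned = TRUE)
}

#' Select chains from a structure
#'
#' Supports heavy-chain-only / light-chain-only training scenarios. Chain
#' detachment can break the receptor-antigen contact criterion, so callers
#' should re-run [sanityCheck()] afterwards.
#'
#' @param s an [AbStructure-class].
#' @param chains character vector of chain identifiers to keep.
#' @return the reduced [AbStructure-class].
#' @export
selectChains <- function(s, chains) {
  a <- s@atoms[s@atoms$chain %in% chains, , drop = FALSE]
  if (!nrow(a)) stop("no atoms left after selecting chains ",
                     paste(chains, collapse = ","))
  rownames(a) <- NULL
  methods::new("AbStructure", atoms = a, role = s@role, cleaned = s@cleaned)
}

#' Label receptor residues that contact the antigen
#'
#' A receptor residue is binding iff any of its heavy atoms lies within
#' \code{cutoff} Angstrom (\code{<=}) of any antigen heavy atom. Distances
#' use a cell-list spatial index that matches the brute-force all-pairs
#' answer exactly.
#'
#' @param receptor cleaned receptor [AbStructure-class].
#' @param antigen cleaned antigen [AbStructure-class].
#' @param cutoff contact cutoff in Angstrom (default 4.5).
#' @return a [BindingLabels-class] over the receptor residues.
#' @examples
#' toy <- makeToyComplex(toyComplexSpec(receptorResidues = 6, interface = c(2, 5)))
#' lab <- labelBindingResidues(toy$receptor, toy$antigen)
#' which(bindingVector(lab))
#' @export
labelBindingResidues <- function(receptor, antigen, cutoff = 4.5) {
  stopifnot_structure(receptor, what = "receptor")
  stopifnot_structure(antigen, what = "antigen")
  ra <- receptor@atoms[receptor@atoms$isHeavy, , drop = FALSE]
  ag <- heavyCoords(antigen)
  if (!nrow(ag)) stop("antigen has no heavy atoms")
  hit <- within_cutoff_cpp(cbind(ra$x, ra$y, ra$z), ag, cutoff)
  res <- residueKeys(receptor)
  akey <- resKey(ra$chain, ra$resno, ra$icode)
  rkey <- resKey(res$chain, res$resno, res$icode)
  perRes <- tapply(hit, factor(akey, levels = rkey), any)
  res$binding <- as.logical(perRes[rkey])
  res$binding[is.na(res$binding)] <- FALSE  # hydrogen-only residues: no heavy atoms
  methods::new("BindingLabels", labels = res, cutoff = cutoff)
}

#' Check that a receptor-antigen pair is in contact
#'
#' TRUE iff at least one receptor heavy atom lies within \code{cutoff} of an
#' antigen heavy atom. Pairs failing this check are excluded from training
#' sets (the check matters most after chain detachment).
#'
#' @inheritParams labelBindingResidues
#' @return logical scalar.
#' @export
sanityCheck <- function(receptor, antigen, cutoff = 4.5) {
  lab <- labelBindingResidues(receptor, antigen, cutoff = cutoff)
  any(lab@labels$binding)
}
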