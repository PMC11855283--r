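#' Read a structure from a PDB file
#'
#' Minimal fixed-width PDB reader for ATOM/HETATM records. Coordinates,
#' occupancy, b-factor, element, altloc and author residue identifiers are
#' parsed; everything else is ignored. Hydrogens (and deuterium) are retained
#' but flagged non-heavy. When a residue carries alternate locations, the
#' highest-occupancy conformer of each atom name is kept (ties: first
#' encountered).
#'
#' @param path path to a PDB file.
#' @param role \code{"receptor"} or \code{"antigen"}.
#' @param chains optional character vector of chain identifiers to keep
#'   (supports heavy-chain-only / light-chain-only workflows).
#' @return an [AbStructure-class].
#' @examples
#' pdb <- makeToyComplex(toyComplexSpec(receptorResidues = 4, interface = 2))
#' tf <- tempfile(fileext = ".pdb")
#' writePDB(pdb$receptor, tf)
#' s <- readPDB(tf, role = "receptor")
#' s
#' @export
readPDB <- function(path, role = c("receptor", "antigen"), chains = NULL) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  parseAtomLines(lines, role = role, chains = chains, src = path)
}

#' @rdname readPDB
#' @param text character vector of PDB lines (alternative to \code{path}).
#' @export
readPDBText <- function(text, role = c("receptor", "antigen"), chains = NULL) {
  role <- match.arg(role)
  parseAtomLines(unlist(strsplit(text, "\n", fixed = TRUE)), role = role,
                 chains = chains, src = "<text>")
}

parseAtomLines <- function(lines, role, chains, src) {
  rec <- substr(lines, 1, 6)
  sel <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!length(sel)) stop("no ATOM/HETATM records in ", src)
  ln <- lines[sel]
  ln <- formatC(ln, width = 80, flag = "-")
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(ln, from, to)))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("cannot parse ", what, " in ", src, " at record: ",
           trimws(ln[bad]))
    }
    v
  }
  name <- trimws(substr(ln, 13, 16))
  element <- toupper(trimws(substr(ln, 77, 78)))
  # element column often absent in hand-made files: fall back on atom name
  miss <- element == ""
  if (any(miss)) element[miss] <- elementFromName(name[miss])
  atoms <- data.frame(
    record = trimws(substr(ln, 1, 6)),
    serial = suppressWarnings(as.integer(substr(ln, 7, 11))),
    name = name,
    altloc = substr(ln, 17, 17),
    resname = trimws(substr(ln, 18, 20)),
    chain = substr(ln, 22, 22),
    resno = as.integer(num(23, 26, "residue number")),
    icode = trimws(substr(ln, 27, 27)),
    x = num(31, 38, "x coordinate"),
    y = num(39, 46, "y coordinate"),
    z = num(47, 54, "z coordinate"),
    occupancy = suppressWarnings(as.numeric(substr(ln, 55, 60))),
    bfactor = suppressWarnings(as.numeric(substr(ln, 61, 66))),
    element = element,
    stringsAsFactors = FALSE
  )
  atoms$occupancy[is.na(atoms$occupancy)] <- 1.0
  atoms$bfactor[is.na(atoms$bfactor)] <- 0.0
  atoms$isHeavy <- !(atoms$element %in% c("H", "D"))
  if (!is.null(chains)) {
    atoms <- atoms[atoms$chain %in% chains, , drop = FALSE]
    if (!nrow(atoms)) stop("no atoms left after chain selection in ", src)
  }
  atoms <- resolveAltloc(atoms)
  rownames(atoms) <- NULL
  methods::new("AbStructure", atoms = atoms, role = role, cleaned = FALSE)
}

# keep the highest-occupancy conformer per (chain, resno, icode, name);
# ties resolved in favour of the first record encountered
resolveAltloc <- function(atoms) {
  alt <- atoms$altloc != " " & atoms$altloc != ""
  if (!any(alt)) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$name, sep = "\r")
  ord <- order(key, -atoms$occupancy, seq_len(nrow(atoms)), method = "radix")
  keep <- ord[!duplicated(key[ord])]
  atoms[sort(keep), , drop = FALSE]
}

elementFromName <- function(name) {
  up <- toupper(name)
  two <- substr(up, 1, 2)
  el <- sub("^[0-9]*", "", up)
  out <- substr(el, 1, 1)
  known2 <- c("SE", "CL", "BR", "FE", "ZN", "MG", "MN", "CU", "NI", "CO",
              "CD", "HG", "NA", "CA")
  out[two %in% known2 & nchar(up) >= 2 & up == two] <- two[two %in% known2 & up == two]
  out[substr(up, 1, 1) %in% c("H", "1", "2", "3") &
        grepl("^[0-9]?H", up)] <- "H"
  out
}

#' Write a structure to a PDB file
#'
#' Emits fixed-width ATOM/HETATM records preserving occupancy and b-factor
#' columns.
#'
#' @param s an [AbStructure-class].
#' @param path output file path.
#' @param bfactor optional numeric vector (one per atom) overriding the
#'   b-factor column, e.g. per-residue prediction scores.
#' @return the path, invisibly.
#' @export
writePDB <- function(s, path, bfactor = NULL) {
  a <- s@atoms
  if (is.null(bfactor)) bfactor <- a$bfactor
  if (length(bfactor) != nrow(a)) stop("bfactor must have one value per atom")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(formatAtomRecords(a, bfactor), con)
  writeLines("END", con)
  invisible(path)
}

formatAtomRecords <- function(a, bfactor) {
  name4 <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
                  ifelse(nchar(a$element) == 2,
                         formatC(a$name, width = -4),
                         paste0(" ", formatC(a$name, width = -3))))
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          substr(a$record, 1, 6), a$serial %% 100000L, name4,
          " ", a$resname, a$chain, a$resno %% 10000L,
          ifelse(a$icode == "", " ", a$icode),
          a$x, a$y, a$z, a$occupancy, bfactor, a$element)
}
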