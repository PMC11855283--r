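# Shared helpers: element tables, RNG scoping, residue keys.

# van der Waals radii (Angstrom), Bondi-style; default covers rare elements.
.vdw_radii <- c(H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                B = 1.92)
.vdw_default <- 1.70

# covalent radii for distance-based bond perception
.cov_radii <- c(H = 0.31, D = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                P = 1.07, SE = 1.20, F = 0.57, CL = 1.02, BR = 1.20, I = 1.39,
                B = 0.84)
.cov_default <- 0.90

.halogens <- c("F", "CL", "BR", "I", "AT")
.metals <- c("LI", "BE", "NA", "MG", "AL", "K", "CA", "MN", "FE", "CO", "NI",
             "CU", "ZN", "RB", "SR", "CS", "BA", "MO", "W", "PT", "AU", "HG",
             "CD", "PB", "V", "CR", "TI", "AG")

.ion_resnames <- c("NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE", "FE2", "CU",
                   "CU1", "NI", "CO", "CD", "HG", "BR", "F", "IOD", "LI", "RB",
                   "CS", "SR", "BA", "AL", "PB", "AG", "AU", "PT", "YB", "SM")

.water_resnames <- c("HOH", "WAT", "DOD", "H2O", "TIP", "TIP3", "SOL")

.standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

# modified residues kept as protein during cleaning
.modified_aa <- c("MSE", "SEC", "PYL", "HYP", "MLY", "CSO", "PTR", "SEP", "TPO")

vdwRadius <- function(element) {
  r <- .vdw_radii[toupper(element)]
  r[is.na(r)] <- .vdw_default
  unname(r)
}

covRadius <- function(element) {
  r <- .cov_radii[toupper(element)]
  r[is.na(r)] <- .cov_default
  unname(r)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

resKey <- function(chain, resno, icode) paste(chain, resno, icode, sep = "\r")

heavyCoords <- function(s) {
  a <- s@atoms[s@atoms$isHeavy, , drop = FALSE]
  cbind(a$x, a$y, a$z)
}

stopifnot_structure <- function(s, needHeavy = TRUE, what = "structure") {
  if (!methods::is(s, "AbStructure")) stop(what, " must be an AbStructure")
  if (needHeavy && sum(s@atoms$isHeavy) < 1)
    stop(what, " contains no heavy atoms")
  invisible(TRUE)
}
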