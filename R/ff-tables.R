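# Reference atom-typing tables for the 18 chemical channels and the packaged
# force-field fallback. No cheminformatics toolkit exists for R in this
# stack, so the pattern semantics (aromaticity, H-bond donor/acceptor, ring
# membership, hybridization) are encoded as explicit per-(residue, atom)
# tables for the standard amino acids, with a connectivity-derived fallback.
# These tables ARE the package's reference definitions (see the methods
# vignette).

.aromatic_atoms <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

.ring_extra <- list(PRO = c("N", "CA", "CB", "CG", "CD"))

# side-chain H-bond acceptors / donors (backbone handled in code)
.acceptor_atoms <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = "ND1", MET = "SD"
)
.donor_atoms <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = "NE2", TRP = "NE1",
  ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG"
)

# sp2 side-chain atoms beyond the aromatic table (carboxyl/amide/guanidinium)
.sp2_extra <- list(
  ASP = c("CG", "OD1", "OD2"), GLU = c("CD", "OE1", "OE2"),
  ASN = c("CG", "OD1", "ND2"), GLN = c("CD", "OE1", "NE2"),
  ARG = c("CZ", "NE", "NH1", "NH2")
)

inNamedList <- function(tbl, resname, name) {
  hit <- tbl[resname]
  mapply(function(h, n) !is.null(h) && n %in% h, hit, name, USE.NAMES = FALSE)
}

# Approximate packaged force-field parameters (fallback when no PQR file is
# supplied). Charges: Amber-94-like backbone and charged-group values with
# element-typed generic side-chain values; an alternative CHARMM-like set.
# Radii: mbondi-style (Amber) and CHARMM-like element radii.
.amber_bb <- c(N = -0.4157, CA = 0.0337, C = 0.5973, O = -0.5679, OXT = -0.80)
.charmm_bb <- c(N = -0.47, CA = 0.07, C = 0.51, O = -0.51, OXT = -0.76)
.amber_side <- list(
  ASP = c(CG = 0.7994, OD1 = -0.8014, OD2 = -0.8014),
  GLU = c(CD = 0.8054, OE1 = -0.8188, OE2 = -0.8188),
  LYS = c(NZ = -0.3854),
  ARG = c(CZ = 0.8076, NE = -0.5295, NH1 = -0.8634, NH2 = -0.8634),
  HIS = c(ND1 = -0.3811, NE2 = -0.5727),
  SER = c(OG = -0.6546), THR = c(OG1 = -0.6761), TYR = c(OH = -0.5579),
  CYS = c(SG = -0.3119), MET = c(SD = -0.2737),
  ASN = c(CG = 0.5833, OD1 = -0.5744, ND2 = -0.9191),
  GLN = c(CD = 0.6951, OE1 = -0.6086, NE2 = -0.9407),
  TRP = c(NE1 = -0.3418)
)
.charmm_side <- list(
  ASP = c(CG = 0.62, OD1 = -0.76, OD2 = -0.76),
  GLU = c(CD = 0.62, OE1 = -0.76, OE2 = -0.76),
  LYS = c(NZ = -0.30),
  ARG = c(CZ = 0.64, NE = -0.70, NH1 = -0.80, NH2 = -0.80),
  HIS = c(ND1 = -0.36, NE2 = -0.61),
  SER = c(OG = -0.66), THR = c(OG1 = -0.66), TYR = c(OH = -0.54),
  CYS = c(SG = -0.23), MET = c(SD = -0.09),
  ASN = c(CG = 0.55, OD1 = -0.55, ND2 = -0.62),
  GLN = c(CD = 0.55, OE1 = -0.55, NE2 = -0.62),
  TRP = c(NE1 = -0.51)
)
.generic_charge <- c(C = 0.0, N = -0.30, O = -0.40, S = -0.15, SE = -0.15,
                     P = 0.40, B = 0.0)
.amber_radius <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.50, S = 1.80,
                   P = 1.85, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85,
                   I = 1.98)
.charmm_radius <- c(H = 1.00, C = 2.00, N = 1.85, O = 1.70, S = 2.00,
                    P = 2.15, SE = 2.10, F = 1.60, CL = 1.90, BR = 2.00,
                    I = 2.15)

lookupCharge <- function(resname, name, element, bb, side, generic) {
  out <- numeric(length(name))
  isBB <- name %in% names(bb)
  out[isBB] <- bb[name[isBB]]
  rest <- which(!isBB)
  for (i in rest) {
    sc <- side[[resname[i]]]
    if (!is.null(sc) && name[i] %in% names(sc)) out[i] <- sc[[name[i]]]
    else {
      g <- generic[element[i]]
      out[i] <- if (is.na(g)) 0 else g
    }
  }
  out
}

lookupRadius <- function(element, tbl, default) {
  r <- tbl[element]
  r[is.na(r)] <- default
  unname(r)
}

internalFFParams <- function(resname, name, element) {
  resname <- toupper(resname); name <- toupper(name); element <- toupper(element)
  list(
    amberCharge = lookupCharge(resname, name, element, .amber_bb, .amber_side, .generic_charge),
    charmmCharge = lookupCharge(resname, name, element, .charmm_bb, .charmm_side, .generic_charge),
    amberRadius = lookupRadius(element, .amber_radius, 1.70),
    charmmRadius = lookupRadius(element, .charmm_radius, 1.90)
  )
}
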