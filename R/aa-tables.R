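# Amino-acid dictionaries used across the package.

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
         GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
         LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
         SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

AA1 <- setNames(names(AA3), AA3)

# Common nonstandard residues mapped to their parent amino acid; anything
# else becomes "X" so downstream features stay defined.
AA_NONSTANDARD <- c(MSE = "MET", SEP = "SER", TPO = "THR", PTR = "TYR",
                    CSO = "CYS", HYP = "PRO", MLY = "LYS", PCA = "GLU",
                    KCX = "LYS", CME = "CYS", SEC = "CYS", PYL = "LYS")

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# Side-chain heavy atoms per residue.  Together with the 4 backbone atoms
# of each of the 20 residues this defines the 167 residue-specific
# heavy-atom classes used by the all-atom pair potential.
SIDECHAIN_ATOMS <- list(
  ALA = "CB",
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

heavy_atom_types <- function() {
  unlist(lapply(names(SIDECHAIN_ATOMS), function(res) {
    paste(res, c(BACKBONE_ATOMS, SIDECHAIN_ATOMS[[res]]), sep = ".")
  }), use.names = FALSE)
}

# Theoretical maximum accessible surface area per residue (Tien et al.
# theoretical values, A^2); used to convert absolute SASA to relative.
MAX_ASA <- c(A = 129, R = 274, N = 195, D = 193, C = 167,
             Q = 225, E = 223, G = 104, H = 224, I = 197,
             L = 201, K = 236, M = 224, F = 240, P = 159,
             S = 155, T = 172, W = 285, Y = 263, V = 174)

# van der Waals radii by element (A) for SASA; fallback 1.70.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
               SE = 1.90)

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

aa3to1 <- function(res3) {
  res3 <- toupper(res3)
  mapped <- AA_NONSTANDARD[res3]
  res3[!is.na(mapped)] <- mapped[!is.na(mapped)]
  out <- AA3[res3]
  out[is.na(out)] <- "X"
  unname(out)
}

aa1to3 <- function(aa) {
  out <- AA1[toupper(aa)]
  out[is.na(out)] <- "UNK"
  unname(out)
}
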