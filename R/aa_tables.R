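# Residue-level lookup tables shared across the package.

# Three-letter -> one-letter, standard residues plus common modified residues
# seen in crystal structures. Unmappable codes become "X" (never match S/T).
AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  # modified residues mapped to their parent
  MSE = "M", SEP = "S", TPO = "T", PTR = "Y", CSO = "C",
  CME = "C", CSD = "C", OCS = "C", KCX = "K", MLY = "K",
  LLP = "K", HYP = "P", PCA = "E", FME = "M", SEC = "C"
)

AA_1TO3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)

AA_20 <- names(AA_1TO3)

aa_three_to_one <- function(aa3) {
  out <- AA_3TO1[toupper(aa3)]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Maximum accessible surface area per residue type
#'
#' Returns the maximum accessible surface area (in square Angstroms) used to
#' normalise absolute solvent accessibility into relative solvent
#' accessibility (RSA). Two published scales are provided: the theoretical
#' maxima of Tien et al. (2013), the default, and the Gly-X-Gly tripeptide
#' values of Miller et al. (1987). The choice of scale shifts RSA values and
#' therefore buried/exposed counts; outputs record which scale was used.
#'
#' @param scale `"tien2013"` (default) or `"miller1987"`.
#' @return Named numeric vector over the 20 standard one-letter codes.
#' @export
max_asa_table <- function(scale = c("tien2013", "miller1987")) {
  scale <- match.arg(scale)
  if (scale == "tien2013") {
    c(A = 129, R = 274, N = 195, D = 193, C = 167,
      E = 223, Q = 225, G = 104, H = 224, I = 197,
      L = 201, K = 236, M = 224, F = 240, P = 159,
      S = 155, T = 172, W = 285, Y = 263, V = 174)
  } else {
    c(A = 113, R = 241, N = 158, D = 151, C = 140,
      E = 183, Q = 189, G = 85,  H = 194, I = 182,
      L = 180, K = 211, M = 204, F = 218, P = 143,
      S = 122, T = 146, W = 259, Y = 229, V = 160)
  }
}

# van der Waals radii by element (A); used by the built-in surface-area
# calculation.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
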