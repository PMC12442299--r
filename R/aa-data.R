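# Amino-acid constant tables shared across the package.

#' @name aa_tables
#' @title Amino-acid lookup tables
#' @description Internal lookup tables: 3-letter to 1-letter codes, theoretical
#'   maximum accessible surface areas (Tien et al. 2013, theoretical column,
#'   in square Angstrom), van der Waals radii by element, atomic masses, and
#'   formal side-chain charges at pH 7.
#' @keywords internal
NULL

.AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

.AA_1TO3 <- stats::setNames(names(.AA_3TO1), unname(.AA_3TO1))

# Theoretical maximum ASA per residue type (Tien et al. 2013), Angstrom^2.
.MAX_ASA <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
  Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
  L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
  S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0
)

# van der Waals radii (Angstrom) for the elements found in protein models.
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

# Atomic masses (unified atomic mass units).
.ATOM_MASS <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, H = 1.008, P = 30.974)

# Formal side-chain charge at pH 7: Asp/Glu -1, Lys/Arg +1, His and all
# others 0; termini uncharged.
.FORMAL_CHARGE <- c(D = -1, E = -1, K = +1, R = +1)

#' Convert 3-letter residue codes to 1-letter codes
#'
#' Total mapping: the 20 standard codes map to their 1-letter equivalents,
#' anything else maps to `"X"`.
#'
#' @param aa3 character vector of 3-letter codes (case-insensitive).
#' @return character vector of 1-letter codes.
#' @export
#' @examples
#' aa3_to_aa1(c("ALA", "GLY", "SEC"))
aa3_to_aa1 <- function(aa3) {
  out <- .AA_3TO1[toupper(aa3)]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Formal residue charge at pH 7
#'
#' @param aa1 character vector of 1-letter residue codes.
#' @return integer vector: Asp/Glu -1, Lys/Arg +1, others 0.
#' @export
residue_formal_charge <- function(aa1) {
  ch <- .FORMAL_CHARGE[toupper(aa1)]
  ch[is.na(ch)] <- 0
  as.integer(unname(ch))
}

#' Theoretical maximum ASA table
#'
#' Per-residue-type maximum accessible surface area used to normalise SASA
#' into relative solvent accessibility (RSA).
#'
#' @return named numeric vector (Angstrom^2) over the 20 standard 1-letter codes.
#' @export
max_asa_table <- function() .MAX_ASA
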