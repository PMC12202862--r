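# Amino-acid alphabet, van-der-Waals radii and max-ASA reference tables.
# All scoring and output ordering uses the fixed alphabetical one-letter order.

AA_ORDER <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Symbols accepted in homolog rows but carrying no amino-acid information:
# ambiguity codes and the rare translated residues are counted as gaps.
NONSTANDARD_AA <- c("X", "B", "Z", "J", "U", "O")

GAP <- "-"

AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

# Common chemically modified residues mapped to their standard parent
# (MODRES-style lookup); anything else non-standard is skipped with a warning.
MODIFIED_PARENT <- c(
  MSE = "MET", SEC = "CYS", PYL = "LYS", CSO = "CYS", SEP = "SER",
  TPO = "THR", PTR = "TYR", MLY = "LYS", HYP = "PRO", KCX = "LYS",
  CME = "CYS", CSD = "CYS", OCS = "CYS", FME = "MET"
)

# Van-der-Waals radii (Angstrom), NACCESS-like element values; unknown heavy
# elements fall back to the default.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
VDW_DEFAULT <- 1.80

# Theoretical maximum accessible surface areas (Angstrom^2) per residue,
# Tien et al. (2013) values, used to normalize SASA into percent RSA.
MAX_ASA <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
  Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
  L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
  S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0
)

#' Amino-acid alphabet used throughout the package
#'
#' @return Character vector of the 20 standard one-letter amino-acid codes in
#'   the fixed (alphabetical) order used for frequency tables and mutation
#'   landscapes.
#' @export
aa_alphabet <- function() AA_ORDER

# Encode aligned sequences as an integer matrix over a set of columns:
# 1..20 for the standard alphabet, 0 for gaps and non-standard symbols.
encode_records <- function(records, columns = NULL) {
  mat <- do.call(rbind, strsplit(records, "", fixed = TRUE))
  if (!is.null(columns)) mat <- mat[, columns, drop = FALSE]
  codes <- match(mat, AA_ORDER)
  codes[is.na(codes)] <- 0L
  matrix(as.integer(codes), nrow = nrow(mat), ncol = ncol(mat))
}
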