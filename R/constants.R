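# Shared constants: amino-acid alphabet, standard genetic code, BLOSUM62.

#' The 20 standard amino acids (one-letter codes)
#'
#' Ordered as in the BLOSUM62 matrix (ARNDCQEGHILKMFPSTWYV).
#' @keywords internal
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_THREE <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)

# Standard nuclear genetic code (NCBI translation table 1); "*" marks stops.
GENETIC_CODE_STD <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*", TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M", ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E", GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

SENSE_CODONS <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD != "*"]

# BLOSUM62 substitution matrix (Henikoff & Henikoff log-odds, half-bits).
BLOSUM62_MAT <- matrix(c(
   4, -1, -2, -2,  0, -1, -1,  0, -2, -1, -1, -1, -1, -2, -1,  1,  0, -3, -2,  0,
  -1,  5,  0, -2, -3,  1,  0, -2,  0, -3, -2,  2, -1, -3, -2, -1, -1, -3, -2, -3,
  -2,  0,  6,  1, -3,  0,  0,  0,  1, -3, -3,  0, -2, -3, -2,  1,  0, -4, -2, -3,
  -2, -2,  1,  6, -3,  0,  2, -1, -1, -3, -4, -1, -3, -3, -1,  0, -1, -4, -3, -3,
   0, -3, -3, -3,  9, -3, -4, -3, -3, -1, -1, -3, -1, -2, -3, -1, -1, -2, -2, -1,
  -1,  1,  0,  0, -3,  5,  2, -2,  0, -3, -2,  1,  0, -3, -1,  0, -1, -2, -1, -2,
  -1,  0,  0,  2, -4,  2,  5, -2,  0, -3, -3,  1, -2, -3, -1,  0, -1, -3, -2, -2,
   0, -2,  0, -1, -3, -2, -2,  6, -2, -4, -4, -2, -3, -3, -2,  0, -2, -2, -3, -3,
  -2,  0,  1, -1, -3,  0,  0, -2,  8, -3, -3, -1, -2, -1, -2, -1, -2, -2,  2, -3,
  -1, -3, -3, -3, -1, -3, -3, -4, -3,  4,  2, -3,  1,  0, -3, -2, -1, -3, -1,  3,
  -1, -2, -3, -4, -1, -2, -3, -4, -3,  2,  4, -2,  2,  0, -3, -2, -1, -2, -1,  1,
  -1,  2,  0, -1, -3,  1,  1, -2, -1, -3, -2,  5, -1, -3, -1,  0, -1, -3, -2, -2,
  -1, -1, -2, -3, -1,  0, -2, -3, -2,  1,  2, -1,  5,  0, -2, -1, -1, -1, -1,  1,
  -2, -3, -3, -3, -2, -3, -3, -3, -1,  0,  0, -3,  0,  6, -4, -2, -2,  1,  3, -1,
  -1, -2, -2, -1, -3, -1, -1, -2, -2, -3, -3, -1, -2, -4,  7, -1, -1, -4, -3, -2,
   1, -1,  1,  0, -1,  0,  0,  0, -1, -2, -2,  0, -1, -2, -1,  4,  1, -3, -2, -2,
   0, -1,  0, -1, -1, -1, -1, -2, -2, -1, -1, -1, -1, -2, -1,  1,  5, -2, -2,  0,
  -3, -3, -4, -4, -2, -2, -3, -2, -2, -3, -2, -3, -1,  1, -4, -3, -2, 11,  2, -3,
  -2, -2, -2, -3, -2, -1, -2, -3,  2, -1, -1, -2, -1,  3, -3, -2, -2,  2,  7, -1,
   0, -3, -3, -3, -1, -2, -2, -3, -3,  3,  1, -2,  1, -1, -2, -2,  0, -3, -1,  4
), nrow = 20, byrow = TRUE, dimnames = list(AA_ORDER, AA_ORDER))

#' BLOSUM62 substitution matrix
#'
#' The standard symmetric 20x20 integer BLOSUM62 matrix, with rows and
#' columns named by one-letter amino-acid codes.
#'
#' @return A 20x20 named integer matrix.
#' @export
#' @examples
#' blosum62()["C", "S"]
blosum62 <- function() {
  BLOSUM62_MAT
}

# --- small internal validators -----------------------------------------------

check_aa <- function(x, arg = "amino acid") {
  bad <- !(x %in% AA_ORDER)
  if (any(bad)) {
    stop(sprintf("invalid %s letter(s): %s (must be one of the 20 standard codes)",
                 arg, paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

check_score_range <- function(score, where = NULL) {
  bad <- which(!is.finite(score) | score < 0 | score > 1)
  if (length(bad)) {
    loc <- if (is.null(where)) sprintf("element %d", bad[1]) else
      sprintf("row %d", where[bad[1]])
    stop(sprintf("score out of [0,1] at %s (value %s)", loc,
                 format(score[bad[1]])), call. = FALSE)
  }
  invisible(score)
}
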