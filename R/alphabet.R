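# Amino-acid alphabet, padding conventions and the bundled BLOSUM62 matrix.

#' The 20-letter amino-acid alphabet used throughout the package
#'
#' Amino acids in the fixed order `ACDEFGHIKLMNPQRSTVWY`. This order defines
#' the slot layout of the one-hot (binary) encoding and the row/column order
#' of [blosum62].
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Padding symbol for window positions beyond a protein terminus
#'
#' Window offsets that fall outside the protein carry this symbol. It one-hot
#' encodes to all zeros, takes property value 0, and has similarity 0 to
#' every residue in the KNN distance, so terminal padding is information-free.
#'
#' @export
PAD_SYMBOL <- "X"

# integer codes: 1..20 = AA_ALPHABET, 21 = pad
.N_AA <- 20L
.PAD_CODE <- 21L

#' BLOSUM62 substitution matrix
#'
#' The standard BLOSUM62 amino-acid substitution matrix restricted to the 20
#' canonical residues, in [AA_ALPHABET] order. Scores range from -4 to 11 and
#' every diagonal entry is the maximum of its row.
#'
#' @format Integer matrix, 20 x 20, dimnames `AA_ALPHABET`.
#' @seealso [normalize_substitution_matrix()]
#' @export
blosum62 <- matrix(c(
   4,  0, -2, -1, -2,  0, -2, -1, -1, -1, -1, -2, -1, -1, -1,  1,  0,  0, -3, -2,  # A
   0,  9, -3, -4, -2, -3, -3, -1, -3, -1, -1, -3, -3, -3, -3, -1, -1, -1, -2, -2,  # C
  -2, -3,  6,  2, -3, -1, -1, -3, -1, -4, -3,  1, -1,  0, -2,  0, -1, -3, -4, -3,  # D
  -1, -4,  2,  5, -3, -2,  0, -3,  1, -3, -2,  0, -1,  2,  0,  0, -1, -2, -3, -2,  # E
  -2, -2, -3, -3,  6, -3, -1,  0, -3,  0,  0, -3, -4, -3, -3, -2, -2, -1,  1,  3,  # F
   0, -3, -1, -2, -3,  6, -2, -4, -2, -4, -3,  0, -2, -2, -2,  0, -2, -3, -2, -3,  # G
  -2, -3, -1,  0, -1, -2,  8, -3, -1, -3, -2,  1, -2,  0,  0, -1, -2, -3, -2,  2,  # H
  -1, -1, -3, -3,  0, -4, -3,  4, -3,  2,  1, -3, -3, -3, -3, -2, -1,  3, -3, -1,  # I
  -1, -3, -1,  1, -3, -2, -1, -3,  5, -2, -1,  0, -1,  1,  2,  0, -1, -2, -3, -2,  # K
  -1, -1, -4, -3,  0, -4, -3,  2, -2,  4,  2, -3, -3, -2, -2, -2, -1,  1, -2, -1,  # L
  -1, -1, -3, -2,  0, -3, -2,  1, -1,  2,  5, -2, -2,  0, -1, -1, -1,  1, -1, -1,  # M
  -2, -3,  1,  0, -3,  0,  1, -3,  0, -3, -2,  6, -2,  0,  0,  1,  0, -3, -4, -2,  # N
  -1, -3, -1, -1, -4, -2, -2, -3, -1, -3, -2, -2,  7, -1, -2, -1, -1, -2, -4, -3,  # P
  -1, -3,  0,  2, -3, -2,  0, -3,  1, -2,  0,  0, -1,  5,  1,  0, -1, -2, -2, -1,  # Q
  -1, -3, -2,  0, -3, -2,  0, -3,  2, -2, -1,  0, -2,  1,  5, -1, -1, -3, -3, -2,  # R
   1, -1,  0,  0, -2,  0, -1, -2,  0, -2, -1,  1, -1,  0, -1,  4,  1, -2, -3, -2,  # S
   0, -1, -1, -1, -2, -2, -2, -1, -1, -1, -1,  0, -1, -1, -1,  1,  5,  0, -2, -2,  # T
   0, -1, -3, -2, -1, -3, -3,  3, -2,  1,  1, -3, -2, -2, -3, -2,  0,  4, -3, -1,  # V
  -3, -2, -4, -3,  1, -2, -2, -3, -3, -2, -1, -4, -4, -2, -3, -3, -2, -3, 11,  2,  # W
  -2, -2, -3, -2,  3, -3,  2, -1, -2, -1, -1, -2, -3, -1, -2, -2, -2, -1,  2,  7   # Y
), nrow = 20L, byrow = TRUE,
   dimnames = list(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                     "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                   c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                     "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")))

# residue character -> integer code; pad -> 21; anything else -> NA
.aa_codes <- function(chars) {
  codes <- match(chars, AA_ALPHABET)
  codes[chars == PAD_SYMBOL] <- .PAD_CODE
  codes
}

# split fragment strings into an n x L integer matrix of residue codes
.code_matrix <- function(fragments, offsets = NULL) {
  if (length(fragments) == 0L) {
    m <- matrix(integer(0), nrow = 0L,
                ncol = if (is.null(offsets)) 0L else length(offsets))
    colnames(m) <- if (is.null(offsets)) NULL else as.character(offsets)
    return(m)
  }
  L <- nchar(fragments[[1L]])
  chars <- matrix(unlist(strsplit(fragments, "", fixed = TRUE), use.names = FALSE),
                  ncol = L, byrow = TRUE)
  m <- matrix(.aa_codes(chars), ncol = L)
  if (any(is.na(m))) {
    stop("illegal residue character in fragment(s): ",
         paste(unique(chars[is.na(m)]), collapse = ", "))
  }
  if (!is.null(offsets)) colnames(m) <- as.character(offsets)
  m
}
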