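# Amino-acid alphabet and scoring schemes shared by the aligners.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA21 <- c(AA20, "X")

#' BLOSUM62 with neutral ambiguity scoring
#'
#' Returns the 21x21 integer substitution matrix used by default: the 20
#' standard residues of BLOSUM62 plus an `X` row/column that scores 0 against
#' everything (unknown residues neither reward nor penalise an alignment).
#'
#' @return Integer matrix with dimnames `A..V, X`.
#' @export
blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- matrix(0L, 21L, 21L, dimnames = list(AA21, AA21))
  m[AA20, AA20] <- e$BLOSUM62[AA20, AA20]
  m
}

#' Scoring scheme for local protein alignment
#'
#' Bundles the substitution matrix, affine gap penalties (a gap of length L
#' costs `gap_open + L * gap_extend`) and the Karlin-Altschul constants used
#' to convert raw scores into bit scores and E-values.  The defaults are the
#' gapped BLOSUM62(11,1) constants lambda = 0.267 nats, K = 0.041.
#'
#' @param substitution_matrix Named integer matrix over the 20 residues + X;
#'   default [blosum62_matrix()].
#' @param gap_open,gap_extend Affine gap penalties (positive integers).
#' @param lambda,K Karlin-Altschul statistical constants.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(substitution_matrix = blosum62_matrix(),
                           gap_open = 11L, gap_extend = 1L,
                           lambda = 0.267, K = 0.041) {
  if (!(gap_open >= gap_extend && gap_extend >= 1)) {
    abort("gap_open >= gap_extend >= 1 is required")
  }
  if (!(lambda > 0 && K > 0)) abort("lambda and K must be positive")
  if (!all(AA21 %in% rownames(substitution_matrix))) {
    abort("substitution matrix must cover the 20 residues plus X")
  }
  structure(
    list(substitution_matrix = substitution_matrix[AA21, AA21],
         gap_open = as.integer(gap_open),
         gap_extend = as.integer(gap_extend),
         lambda = lambda, K = K),
    class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("<scoring_scheme> gap_open=", x$gap_open, " gap_extend=", x$gap_extend,
      " lambda=", x$lambda, " K=", x$K, "\n", sep = "")
  invisible(x)
}

# Encode a protein string as 0-based integer codes; anything outside the
# 20-letter alphabet maps to X (code 20).
encode_seq <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, AA21)
  idx[is.na(idx)] <- 21L
  as.integer(idx - 1L)
}

validate_protein_seq <- function(seq, what = "sequence") {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    abort(paste(what, "must be a non-empty string"))
  }
  invisible(seq)
}
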