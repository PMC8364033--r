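#' Alignment scoring scheme
#'
#' Collects the substitution scores, affine gap penalties and Karlin-Altschul
#' bitscore parameters used by every alignment-based stage. Defaults follow
#' BLAST-family conventions: blastn-style +2/-3 with gap open 5 / extend 2 for
#' nucleotides, BLOSUM62 with gap open 11 / extend 1 for proteins. The
#' gapped Karlin-Altschul parameters for those settings (nucleotide
#' lambda = 0.625, K = 0.41; protein lambda = 0.267, K = 0.041) convert raw
#' scores to bitscores as \code{(lambda * S - ln K) / ln 2}.
#'
#' N never matches any base (it scores as a mismatch, including against N);
#' amino acids outside the BLOSUM62 alphabet (X, J, O, U) score 0 against
#' everything (neutral).
#'
#' @param nt_match,nt_mismatch nucleotide match/mismatch scores.
#' @param nt_gap_open,nt_gap_extend nucleotide gap penalties (positive; a gap
#'   of length k costs \code{open + k * extend}).
#' @param protein_matrix protein substitution matrix name ("BLOSUM62").
#' @param aa_gap_open,aa_gap_extend protein gap penalties (positive).
#' @param nt_lambda,nt_k,aa_lambda,aa_k Karlin-Altschul parameters.
#' @return object of class \code{scoring_scheme}.
#' @export
scoring_scheme <- function(nt_match = 2L, nt_mismatch = -3L,
                           nt_gap_open = 5L, nt_gap_extend = 2L,
                           protein_matrix = "BLOSUM62",
                           aa_gap_open = 11L, aa_gap_extend = 1L,
                           nt_lambda = 0.625, nt_k = 0.41,
                           aa_lambda = 0.267, aa_k = 0.041) {
  if (nt_gap_open <= 0 || nt_gap_extend <= 0 || aa_gap_open <= 0 ||
      aa_gap_extend <= 0)
    stop("gap penalties must be strictly positive")
  if (nt_lambda <= 0 || nt_k <= 0 || aa_lambda <= 0 || aa_k <= 0)
    stop("Karlin-Altschul parameters must be strictly positive")
  if (!identical(protein_matrix, "BLOSUM62"))
    stop("only BLOSUM62 is supported as protein matrix")
  obj <- list(
    nt_match = as.integer(nt_match), nt_mismatch = as.integer(nt_mismatch),
    nt_gap_open = as.integer(nt_gap_open),
    nt_gap_extend = as.integer(nt_gap_extend),
    protein_matrix = protein_matrix,
    aa_gap_open = as.integer(aa_gap_open),
    aa_gap_extend = as.integer(aa_gap_extend),
    nt_lambda = nt_lambda, nt_k = nt_k,
    aa_lambda = aa_lambda, aa_k = aa_k)
  obj$nt_matrix <- nt_score_matrix(obj$nt_match, obj$nt_mismatch)
  obj$aa_matrix <- aa_score_matrix()
  class(obj) <- "scoring_scheme"
  obj
}

# 5x5 integer matrix over A,C,G,T,N; N scores mismatch against everything.
nt_score_matrix <- function(match, mismatch) {
  m <- matrix(as.integer(mismatch), 5, 5,
              dimnames = list(c("A", "C", "G", "T", "N"),
                              c("A", "C", "G", "T", "N")))
  diag(m)[1:4] <- as.integer(match)
  m
}

# 27x27 integer matrix over A..Z plus '*', populated from BLOSUM62.
# Letters absent from BLOSUM62 (J, O, U) and X are neutral (0 everywhere).
aa_score_matrix <- function() {
  b62 <- get_blosum62()
  letters27 <- c(LETTERS, "*")
  m <- matrix(0L, 27, 27, dimnames = list(letters27, letters27))
  common <- intersect(rownames(b62), letters27)
  common <- setdiff(common, "X") # keep X neutral per scheme contract
  m[common, common] <- as.integer(b62[common, common])
  m
}

get_blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

#' Convert a raw alignment score to a bitscore
#'
#' \code{(lambda * score - ln K) / ln 2} with the scheme's parameters for the
#' given alphabet.
#'
#' @param score raw score in substitution-matrix units.
#' @param scheme a \code{\link{scoring_scheme}}.
#' @param alphabet "nt" or "aa".
#' @return bitscore in bits.
#' @export
bitscore <- function(score, scheme = scoring_scheme(), alphabet = c("aa", "nt")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "aa")
    (scheme$aa_lambda * score - log(scheme$aa_k)) / log(2)
  else
    (scheme$nt_lambda * score - log(scheme$nt_k)) / log(2)
}
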