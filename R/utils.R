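#' @useDynLib metapang, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats hclust cutree as.dist cor rbinom rnorm runif aggregate setNames
#' @importFrom utils write.table read.table
NULL

# Derive a reproducible sub-seed for a named stage from the master seed.
# Keeps results stable when stages are rerun in isolation.
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) + 97L * h) %% .Machine$integer.max)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate nucleotide gene sequences to proteins
#'
#' Standard genetic code, no ambiguity handling beyond what the sequences
#' contain. Input genes are expected to be in frame (length a multiple of 3).
#'
#' @param x named character vector of nucleotide sequences.
#' @return named character vector of amino-acid sequences.
#' @export
translate_genes <- function(x) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(x),
                                           no.init.codon = TRUE))
  names(aa) <- names(x)
  aa
}

# shared argument check: non-empty single character sequence
check_seq <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stop(what, " must be a non-empty character string", call. = FALSE)
  invisible(toupper(x))
}

#' Adjusted Rand index between two labelings
#'
#' Thin wrapper used to compare recovered partitions against planted truth.
#' @param a,b label vectors over the same elements.
#' @return scalar ARI.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- ai * bj / choose(n, 2)
  maxidx <- (ai + bj) / 2
  if (maxidx == expected) return(1)
  (nij - expected) / (maxidx - expected)
}
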