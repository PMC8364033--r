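# Independent oracles, written separately from the package kernels.

# Quadratic-space affine-gap local alignment DP in plain R. Returns only the
# optimal score (all-cells maximum); gap of length k costs open + k * extend.
sw_score_oracle <- function(q, s, submat, gap_open, gap_extend) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  m <- length(qc); n <- length(sc)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  open <- gap_open + gap_extend
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - open, E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - open, F[i - 1, j] - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + submat[qc[i - 1], sc[j - 1]],
                     E[i, j], F[i, j])
    }
  }
  max(H)
}

# Biostrings local pairwiseAlignment score (second, independent route).
biostrings_nt_score <- function(q, s, scheme) {
  mat <- matrix(scheme$nt_mismatch, 4, 4,
                dimnames = list(c("A", "C", "G", "T"),
                                c("A", "C", "G", "T")))
  diag(mat) <- scheme$nt_match
  Biostrings::pairwiseAlignment(q, s, type = "local",
                                substitutionMatrix = mat,
                                gapOpening = scheme$nt_gap_open,
                                gapExtension = scheme$nt_gap_extend,
                                scoreOnly = TRUE)
}

biostrings_aa_score <- function(q, s, scheme) {
  Biostrings::pairwiseAlignment(q, s, type = "local",
                                substitutionMatrix = "BLOSUM62",
                                gapOpening = scheme$aa_gap_open,
                                gapExtension = scheme$aa_gap_extend,
                                scoreOnly = TRUE)
}

# Dense reference MCL, no pruning, clusters read off as connected
# components of the converged matrix support.
mcl_oracle <- function(A, inflation, max_iter = 300) {
  diag(A) <- 0
  loop <- apply(A, 1, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), "/")
  for (i in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    done <- max(abs(M2 - M)) < 1e-12
    M <- M2
    if (done) break
  }
  supp <- (M > 1e-7) | t(M > 1e-7)
  diag(supp) <- TRUE
  comp <- components_of(supp)
  split(rownames(A), comp)
}
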