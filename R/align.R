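#' Local nucleotide alignment with identity and coverage statistics
#'
#' Smith-Waterman local alignment with affine gaps. Both strands of the query
#' are evaluated against the subject (the query is reverse-complemented) and
#' the best-scoring alignment is reported; on a score tie the forward strand
#' wins. Percent identity is computed over aligned residue pairs (gap columns
#' excluded from the denominator, the BLAST "identities" convention); query
#' and subject coverage are the aligned span divided by the full sequence
#' length. N never counts as a match.
#'
#' @param query,subject non-empty nucleotide strings over A,C,G,T,N.
#' @param scheme a \code{\link{scoring_scheme}}.
#' @return a one-row data.frame of class \code{alignment_result} with columns
#'   query_id, subject_id, score, bitscore, percent_identity, aligned_length,
#'   matches, query_coverage, subject_coverage, strand, qstart, qend, sstart,
#'   send.
#' @export
align_nt <- function(query, subject, scheme = scoring_scheme()) {
  q <- check_seq(query, "query")
  s <- check_seq(subject, "subject")
  fwd <- cpp_align(q, s, scheme$nt_matrix, scheme$nt_gap_open,
                   scheme$nt_gap_extend, FALSE)
  rev <- cpp_align(revcomp(q), s, scheme$nt_matrix, scheme$nt_gap_open,
                   scheme$nt_gap_extend, FALSE)
  if (rev$score > fwd$score) {
    aln <- rev; strand <- "reverse"
  } else {
    aln <- fwd; strand <- "forward"
  }
  aln_result(aln, nchar(q), nchar(s), strand, scheme, "nt",
             query_id = names(query), subject_id = names(subject))
}

#' Local protein alignment under BLOSUM62 with bitscores
#'
#' Smith-Waterman local alignment of two protein sequences under the scheme's
#' substitution matrix; the bitscore is derived from the raw score via the
#' scheme's Karlin-Altschul parameters. X scores as neutral (0).
#'
#' @inheritParams align_nt
#' @return a one-row \code{alignment_result} data.frame (strand is "forward").
#' @export
align_aa <- function(query, subject, scheme = scoring_scheme()) {
  q <- check_seq(query, "query")
  s <- check_seq(subject, "subject")
  aln <- cpp_align(q, s, scheme$aa_matrix, scheme$aa_gap_open,
                   scheme$aa_gap_extend, TRUE)
  aln_result(aln, nchar(q), nchar(s), "forward", scheme, "aa",
             query_id = names(query), subject_id = names(subject))
}

aln_result <- function(aln, qlen, slen, strand, scheme, alphabet,
                       query_id = NULL, subject_id = NULL) {
  empty <- aln$score <= 0 || aln$pairs == 0
  out <- data.frame(
    query_id = if (is.null(query_id)) NA_character_ else query_id,
    subject_id = if (is.null(subject_id)) NA_character_ else subject_id,
    score = aln$score,
    bitscore = bitscore(aln$score, scheme, alphabet),
    percent_identity = if (empty) 0 else 100 * aln$matches / aln$pairs,
    aligned_length = aln$cols,
    matches = aln$matches,
    query_coverage = if (empty) 0 else (aln$qend - aln$qstart + 1) / qlen,
    subject_coverage = if (empty) 0 else (aln$send - aln$sstart + 1) / slen,
    strand = strand,
    qstart = aln$qstart, qend = aln$qend,
    sstart = aln$sstart, send = aln$send,
    stringsAsFactors = FALSE)
  class(out) <- c("alignment_result", class(out))
  out
}

#' BLAST-tabular-style alignment report
#'
#' Aligns each query against each subject and returns a tabular summary
#' (qseqid, sseqid, pident, length, bitscore, qcovs), the debug view used
#' when inspecting threshold behavior.
#'
#' @param queries,subjects named character vectors of sequences.
#' @param alphabet "nt" (both strands) or "aa".
#' @param scheme a \code{\link{scoring_scheme}}.
#' @return data.frame with one row per query/subject pair.
#' @export
alignment_table <- function(queries, subjects, alphabet = c("nt", "aa"),
                            scheme = scoring_scheme()) {
  alphabet <- match.arg(alphabet)
  f <- if (alphabet == "nt") align_nt else align_aa
  rows <- lapply(seq_along(queries), function(i) {
    do.call(rbind, lapply(seq_along(subjects), function(j) {
      a <- f(stats::setNames(queries[[i]], names(queries)[i]),
             stats::setNames(subjects[[j]], names(subjects)[j]), scheme)
      data.frame(qseqid = names(queries)[i], sseqid = names(subjects)[j],
                 pident = a$percent_identity, length = a$aligned_length,
                 bitscore = a$bitscore, qcovs = a$query_coverage,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
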