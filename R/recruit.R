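#' Recruit one sample's reads onto a gene catalog
#'
#' Each read is locally aligned (both strands) against the catalog and
#' accepted iff its percent identity is at least \code{recruit_identity} and
#' the alignment covers at least \code{recruit_coverage} of the read
#' (defaults 80% / 0.70). An accepted read is assigned to the single best
#' gene: highest identity, then longest alignment, then lowest gene index
#' (best-hit-only; no fractional splitting).
#'
#' Candidate genes are found by shared 13-mers (top candidates per strand are
#' aligned); \code{exact = TRUE} aligns each read against every gene on both
#' strands.
#'
#' @param reads named character vector of read sequences (or a data.frame
#'   with read_id and seq columns as produced by \code{\link{sample_reads}}).
#' @param catalog named character vector of gene nucleotide sequences.
#' @param config a \code{\link{threshold_config}}.
#' @param scheme a \code{\link{scoring_scheme}}.
#' @param exact disable the seeded candidate search.
#' @param max_candidates seeded mode: candidate genes aligned per strand.
#' @return data.frame of accepted reads: read_id, gene_id, identity,
#'   aln_len, sstart, send, qcov, strand; attribute \code{"n_unassigned"}.
#' @export
recruit_reads <- function(reads, catalog, config = threshold_config(),
                          scheme = scoring_scheme(), exact = FALSE,
                          max_candidates = 5L) {
  if (is.data.frame(reads)) reads <- setNames(reads$seq, reads$read_id)
  if (length(reads) == 0 || length(catalog) == 0)
    stop("reads and catalog must be non-empty")
  if (is.null(names(reads))) names(reads) <- sprintf("r%06d",
                                                     seq_along(reads))
  rc <- revcomp(reads)
  res <- cpp_recruit(unname(reads), unname(rc), unname(catalog), 13L,
                     scheme$nt_matrix, scheme$nt_gap_open,
                     scheme$nt_gap_extend, config$recruit_identity,
                     config$recruit_coverage, as.integer(max_candidates),
                     exact)
  out <- data.frame(read_id = names(reads)[res$read],
                    gene_id = names(catalog)[res$gene],
                    identity = res$identity, aln_len = res$aln_len,
                    sstart = res$sstart, send = res$send,
                    qcov = res$qcov,
                    strand = ifelse(res$strand == 0, "+", "-"),
                    stringsAsFactors = FALSE)
  attr(out, "n_unassigned") <- length(reads) - nrow(out)
  out
}

#' Mean per-base coverage per gene across samples
#'
#' Coverage of a gene in a sample is the total number of bases aligned to it
#' (sum of subject-side aligned spans of accepted reads) divided by the gene
#' length; genes with no reads get 0.
#'
#' @param assignments named list (one element per sample) of data.frames
#'   from \code{\link{recruit_reads}}.
#' @param catalog named character vector of gene sequences (defines entity
#'   order and lengths).
#' @param metadata optional sample metadata (sample_id, depth_m, date).
#' @return a \code{coverage_profile}: numeric matrix genes x samples with a
#'   \code{"samples"} attribute carrying the metadata.
#' @export
coverage_per_gene <- function(assignments, catalog, metadata = NULL) {
  samples <- names(assignments)
  m <- matrix(0, length(catalog), length(samples),
              dimnames = list(names(catalog), samples))
  for (s in samples) {
    a <- assignments[[s]]
    if (is.null(a) || nrow(a) == 0) next
    bases <- tapply(a$send - a$sstart + 1, a$gene_id, sum)
    m[names(bases), s] <- as.numeric(bases)
  }
  m <- m / nchar(catalog)
  if (!is.null(metadata)) {
    metadata <- metadata[match(samples, metadata$sample_id), , drop = FALSE]
  }
  structure(m, samples = metadata, class = c("coverage_profile", "matrix",
                                             "array"))
}

#' Aggregate a gene-level profile to orthogroups or populations
#'
#' The aggregate value is the mean of member-gene coverages, including
#' members with zero coverage. Genes absent from the membership map are
#' dropped.
#'
#' @param gene_profile a \code{coverage_profile} (genes x samples).
#' @param membership named character vector gene_id -> aggregate id.
#' @return a \code{coverage_profile} (aggregates x samples).
#' @export
aggregate_coverage <- function(gene_profile, membership) {
  genes <- intersect(rownames(gene_profile), names(membership))
  grp <- membership[genes]
  sub <- unclass(gene_profile)[genes, , drop = FALSE]
  agg <- rowsum(sub, grp) / as.vector(table(grp)[sort(unique(grp))])
  structure(as.matrix(agg), samples = attr(gene_profile, "samples"),
            class = c("coverage_profile", "matrix", "array"))
}

#' Scale a coverage profile to [0, 1] per entity
#'
#' Each row is divided by its maximum over samples; all-zero rows stay zero.
#' Idempotent.
#'
#' @param profile matrix entities x samples.
#' @return matrix of the same shape.
#' @export
scale_profiles <- function(profile) {
  m <- unclass(profile)
  mx <- apply(m, 1, max)
  mx[mx == 0] <- 1
  out <- m / mx
  attributes(out) <- attributes(profile)
  if (is.null(dim(out))) dim(out) <- dim(m)
  out
}

#' Export read assignments as a minimal SAM file
#'
#' Minimal dialect: @HD and one @SQ line per catalog gene, then one
#' alignment line per accepted read (flag 0/16 by strand, POS = subject
#' start, MAPQ 255, CIGAR \code{<aln_len>M}, sequence and quality "*").
#'
#' @param assignments data.frame from \code{\link{recruit_reads}}.
#' @param catalog named character vector of gene sequences.
#' @param path output file.
#' @return invisibly, the path.
#' @export
assignments_to_sam <- function(assignments, catalog, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(catalog), nchar(catalog)),
             con)
  if (nrow(assignments) > 0) {
    a <- assignments[order(assignments$gene_id, assignments$sstart), ]
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
                       a$read_id, ifelse(a$strand == "+", 0L, 16L),
                       a$gene_id, a$sstart, a$send - a$sstart + 1L), con)
  }
  invisible(path)
}
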