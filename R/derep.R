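seq_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character())
  unique(substring(seq, 1:(L - k + 1), k:L))
}

#' Greedy incremental gene dereplication (CD-HIT-EST semantics)
#'
#' Genes are sorted by decreasing length (ties by id) and processed greedily:
#' each gene joins the best-scoring existing representative it matches at
#' \code{derep_identity} percent local identity (identity computed over the
#' aligned region) with the alignment covering at least \code{derep_coverage}
#' of the shorter (member) sequence, both strands considered; otherwise it
#' founds a new representative. "Best-scoring" is highest identity, then
#' longest alignment, then earliest representative (accurate mode made
#' deterministic; forward strand wins exact ties).
#'
#' Candidate representatives are prefiltered by shared 13-mers (guaranteed
#' plentiful at 95% identity); \code{exact = TRUE} compares against every
#' representative instead.
#'
#' @param genes named character vector of nucleotide gene sequences.
#' @param config a \code{\link{threshold_config}}.
#' @param scheme a \code{\link{scoring_scheme}}.
#' @param exact disable the k-mer prefilter.
#' @return list with \code{representatives} (named character vector, in
#'   founding order) and \code{members} (data.frame gene_id,
#'   representative_id).
#' @export
dereplicate_genes <- function(genes, config = threshold_config(),
                              scheme = scoring_scheme(), exact = FALSE) {
  if (length(genes) == 0) stop("empty gene list")
  if (is.null(names(genes)) || any(names(genes) == ""))
    stop("genes must be named")
  if (anyDuplicated(names(genes))) stop("duplicate gene ids")
  k <- 13L
  ord <- order(-nchar(genes), names(genes))
  genes <- genes[ord]
  rc <- revcomp(genes)
  rep_idx <- integer()          # indices (into genes) of representatives
  assign_rep <- integer(length(genes))
  kenv <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(genes)) {
    cand <- integer()
    if (length(rep_idx) > 0) {
      if (exact) {
        cand <- seq_along(rep_idx)
      } else {
        kms <- unique(c(seq_kmers(genes[i], k), seq_kmers(rc[i], k)))
        hits <- unlist(mget(kms, envir = kenv, ifnotfound = list(NULL)),
                       use.names = FALSE)
        cand <- sort(unique(hits))
      }
    }
    best <- 0L
    if (length(cand) > 0) {
      nc <- length(cand)
      seqs <- c(genes[i], rc[i], genes[rep_idx[cand]])
      res <- cpp_align_pairs(unname(seqs),
                             qi = rep(c(1L, 2L), each = nc),
                             si = rep(2L + seq_len(nc), times = 2L),
                             scheme$nt_matrix, scheme$nt_gap_open,
                             scheme$nt_gap_extend, FALSE)
      ident <- ifelse(res$pairs > 0, 100 * res$matches / res$pairs, 0)
      qcov <- ifelse(res$pairs > 0,
                     (res$qend - res$qstart + 1) / nchar(genes[i]), 0)
      ok <- which(ident >= config$derep_identity &
                  qcov >= config$derep_coverage)
      if (length(ok) > 0) {
        # order: identity desc, alignment length desc, rep order asc,
        # forward strand (rows 1..nc) before reverse
        rep_of_row <- rep(cand, times = 2L)
        strand_of_row <- rep(c(0L, 1L), each = nc)
        o <- ok[order(-ident[ok], -res$cols[ok], rep_of_row[ok],
                      strand_of_row[ok])][1]
        best <- rep_of_row[o]
      }
    }
    if (best > 0L) {
      assign_rep[i] <- best
    } else {
      rep_idx <- c(rep_idx, i)
      assign_rep[i] <- length(rep_idx)
      for (km in seq_kmers(genes[i], k)) {
        kenv[[km]] <- c(kenv[[km]], length(rep_idx))
      }
    }
  }
  reps <- genes[rep_idx]
  list(representatives = reps,
       members = data.frame(gene_id = names(genes),
                            representative_id = names(reps)[assign_rep],
                            stringsAsFactors = FALSE))
}

#' Build population genomes: pooled, dereplicated gene catalogs
#'
#' For each population in the partition, pools the genes of its member
#' genomes and dereplicates them into the population's gene catalog.
#'
#' @param partition data.frame (genome_id, population_id) from
#'   \code{\link{cluster_populations}}.
#' @param genes data.frame with gene_id, genome_id, seq_nt (and optionally
#'   seq_aa), e.g. the \code{genes} table of a \code{community}.
#' @param config a \code{\link{threshold_config}}.
#' @param scheme a \code{\link{scoring_scheme}}.
#' @param exact disable the dereplication k-mer prefilter.
#' @return named list of \code{population_genome} objects: population_id,
#'   member genomes, catalog_nt / catalog_aa (representative sequences) and
#'   the member map.
#' @export
build_population_genomes <- function(partition, genes,
                                     config = threshold_config(),
                                     scheme = scoring_scheme(),
                                     exact = FALSE) {
  orphan <- setdiff(unique(genes$genome_id), partition$genome_id)
  if (length(orphan) > 0) {
    bad <- genes$gene_id[genes$genome_id == orphan[1]][1]
    stop("gene ", bad, " belongs to genome ", orphan[1],
         " which is absent from the partition")
  }
  pops <- list()
  for (pid in sort(unique(partition$population_id))) {
    members <- partition$genome_id[partition$population_id == pid]
    sub <- genes[genes$genome_id %in% members, ]
    cat <- dereplicate_genes(setNames(sub$seq_nt, sub$gene_id), config,
                             scheme, exact)
    aa <- if ("seq_aa" %in% names(sub))
      setNames(sub$seq_aa, sub$gene_id)[names(cat$representatives)]
    else NULL
    pops[[pid]] <- structure(list(
      population_id = pid, members = members,
      catalog_nt = cat$representatives, catalog_aa = aa,
      member_map = cat$members), class = "population_genome")
  }
  pops
}

#' Drop populations with no recruited reads
#'
#' Removes populations whose coverage row is zero in every sample (the
#' locally-irrelevant reference rule); a single mapped read anywhere retains
#' the population.
#'
#' @param populations named list of \code{population_genome} objects.
#' @param coverage matrix populations x samples of mean coverage.
#' @return the retained sublist, with removed ids in attribute
#'   \code{"removed"}.
#' @export
filter_locally_relevant <- function(populations, coverage) {
  ids <- names(populations)
  missing <- setdiff(ids, rownames(coverage))
  if (length(missing) > 0)
    stop("coverage missing for population(s): ",
         paste(missing, collapse = ", "))
  keep <- ids[rowSums(coverage[ids, , drop = FALSE]) > 0]
  out <- populations[keep]
  attr(out, "removed") <- setdiff(ids, keep)
  out
}
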