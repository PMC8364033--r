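concat_contigs <- function(genome, sep_n = 50L) {
  paste(genome, collapse = strrep("N", sep_n))
}

#' Fragment-based average nucleotide identity between two genomes
#'
#' ANIb-style: the query genome is cut, contig by contig, into consecutive
#' fragments of \code{ani_fragment_length} bp (a trailing remainder is kept);
#' each fragment is locally aligned against the whole subject genome (both
#' strands) and retained when its identity and fragment coverage pass the
#' acceptance thresholds (defaults 30% / 0.70). The directional ANI is the
#' mean identity of retained fragments; the symmetrized ANI averages the two
#' directions (a direction with no accepted fragment is dropped; the value is
#' missing when both directions fail).
#'
#' By default each fragment is aligned inside a window located by exact
#' k-mer seeding; \code{exact = TRUE} aligns against the full subject, and
#' the two agree on all tested inputs (see package tests).
#'
#' @param genome_a,genome_b named character vectors of contigs.
#' @param config a \code{\link{threshold_config}}.
#' @param scheme a \code{\link{scoring_scheme}}.
#' @param exact skip seeding and run the full dynamic program.
#' @return list with \code{ani} (symmetrized, NA if missing), \code{ab},
#'   \code{ba} (directional values), and fragment counts.
#' @export
compute_ani <- function(genome_a, genome_b, config = threshold_config(),
                        scheme = scoring_scheme(), exact = FALSE) {
  if (length(genome_a) == 0 || sum(nchar(genome_a)) == 0 ||
      length(genome_b) == 0 || sum(nchar(genome_b)) == 0)
    stop("genomes must be non-empty")
  ab <- ani_directional(genome_a, genome_b, config, scheme, exact)
  ba <- ani_directional(genome_b, genome_a, config, scheme, exact)
  vals <- c(ab$ani, ba$ani)
  ani <- if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  list(ani = ani, ab = ab$ani, ba = ba$ani,
       n_fragments = ab$n_fragments + ba$n_fragments,
       n_accepted = ab$n_accepted + ba$n_accepted)
}

ani_directional <- function(qg, sg, config, scheme, exact) {
  subj <- concat_contigs(sg)
  subj_rc <- revcomp(subj)
  frags <- list()
  for (contig in qg) {
    if (nchar(contig) == 0) next
    df <- cpp_ani_fragments(contig, subj, subj_rc,
                            config$ani_fragment_length,
                            scheme$nt_matrix, scheme$nt_gap_open,
                            scheme$nt_gap_extend,
                            seed_k = 13L, margin = 64L, exact = exact)
    frags[[length(frags) + 1L]] <- df
  }
  df <- do.call(rbind, frags)
  keep <- df$identity >= config$fragment_accept_identity &
    df$coverage >= config$fragment_accept_coverage
  list(ani = if (any(keep)) mean(df$identity[keep]) else NA_real_,
       n_fragments = nrow(df), n_accepted = sum(keep))
}

#' Pairwise ANI matrix over a genome collection
#'
#' Symmetric percent-identity matrix (diagonal 100) from
#' \code{\link{compute_ani}} on every genome pair. Pairs with no accepted
#' fragment in either direction are NA (missing, not 0). The largest
#' directional asymmetry is reported in the \code{"max_directional_diff"}
#' attribute and the full directional matrix in \code{"directional"}.
#'
#' @param genomes named list; each element a character vector of contigs.
#' @inheritParams compute_ani
#' @return numeric matrix of class \code{ani_matrix}.
#' @export
ani_matrix <- function(genomes, config = threshold_config(),
                       scheme = scoring_scheme(), exact = FALSE) {
  ids <- names(genomes)
  if (is.null(ids) || any(ids == ""))
    stop("genomes must be a named list")
  n <- length(ids)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  dir <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(m) <- 100
  diag(dir) <- 100
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        a <- compute_ani(genomes[[i]], genomes[[j]], config, scheme, exact)
        m[i, j] <- m[j, i] <- a$ani
        dir[i, j] <- a$ab
        dir[j, i] <- a$ba
      }
    }
  }
  attr(m, "directional") <- dir
  offdiag <- abs(dir - t(dir))
  attr(m, "max_directional_diff") <-
    if (n >= 2) max(offdiag[upper.tri(offdiag)], na.rm = TRUE) else 0
  class(m) <- c("ani_matrix", class(m))
  m
}

#' Cluster genomes into populations at an ANI threshold
#'
#' Agglomerative clustering on distance \code{100 - ANI} with the tree cut at
#' \code{100 - threshold}: single linkage reproduces SLc-style population
#' delineation, complete linkage CLc-style. Missing ANI values are treated as
#' distance 100 (conservative non-merging). Populations are labeled P01,
#' P02, ... in order of their first member.
#'
#' @param ani an \code{\link{ani_matrix}} (or plain symmetric matrix).
#' @param linkage "single" or "complete".
#' @param threshold percent ANI boundary (default 95).
#' @return data.frame with columns genome_id, population_id.
#' @export
cluster_populations <- function(ani, linkage = c("single", "complete"),
                                threshold = 95) {
  linkage <- match.arg(linkage)
  if (is.null(dim(ani)) || nrow(ani) < 1) stop("need at least one genome")
  ids <- rownames(ani)
  if (nrow(ani) == 1)
    return(data.frame(genome_id = ids, population_id = "P01",
                      stringsAsFactors = FALSE))
  d <- 100 - unclass(ani)
  d[is.na(d)] <- 100
  hc <- hclust(as.dist(d), method = linkage)
  cl <- cutree(hc, h = 100 - threshold)
  # relabel in order of first appearance
  first <- match(unique(cl[ids]), cl[ids])
  relabel <- setNames(seq_along(first), cl[ids][first])
  data.frame(genome_id = ids,
             population_id = sprintf("P%02d", relabel[as.character(cl[ids])]),
             stringsAsFactors = FALSE, row.names = NULL)
}
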