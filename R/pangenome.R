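#' Protein similarity graph with minbit filtering
#'
#' All-vs-all local protein alignment across the pooled population-genome
#' catalogs. For a pair (a, b),
#' \code{minbit = bitscore(a, b) / min(selfbitscore(a), selfbitscore(b))};
#' an undirected edge is kept iff minbit is at least the configured
#' threshold (default 0.5), which removes weak partial matches. Scoring is
#' symmetric, so the single alignment per pair equals the best of the two
#' directions.
#'
#' Pairs are prefiltered by a shared amino-acid 5-mer (pairs strong enough to
#' pass minbit 0.5 always share one); \code{exact = TRUE} aligns every pair.
#'
#' @param catalogs data.frame with columns gene_id, population_id, seq_aa
#'   (one row per catalog representative), or a named list of
#'   \code{population_genome} objects.
#' @param config a \code{\link{threshold_config}}.
#' @param scheme a \code{\link{scoring_scheme}}.
#' @param exact disable the k-mer prefilter.
#' @return list of class \code{similarity_graph}: \code{nodes} (gene_id,
#'   population_id, self_bitscore), \code{edges} (gene_a, gene_b, bitscore,
#'   minbit).
#' @export
build_graph <- function(catalogs, config = threshold_config(),
                        scheme = scoring_scheme(), exact = FALSE) {
  if (is.list(catalogs) && !is.data.frame(catalogs))
    catalogs <- catalog_table(catalogs)
  stopifnot(all(c("gene_id", "population_id", "seq_aa") %in% names(catalogs)))
  if (any(nchar(catalogs$seq_aa) == 0)) stop("empty protein sequence")
  seqs <- catalogs$seq_aa
  self_raw <- cpp_self_scores(seqs, scheme$aa_matrix, TRUE)
  if (any(self_raw <= 0))
    stop("protein with non-positive self-score: ",
         catalogs$gene_id[which(self_raw <= 0)[1]])
  self_bits <- bitscore(self_raw, scheme, "aa")
  if (exact) {
    n <- length(seqs)
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pairs <- data.frame(i = idx[, 1], j = idx[, 2])
  } else {
    pairs <- cpp_kmer_pairs(seqs, 5L, TRUE)
  }
  edges <- data.frame(gene_a = character(), gene_b = character(),
                      bitscore = numeric(), minbit = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) > 0) {
    res <- cpp_align_pairs(seqs, pairs$i, pairs$j, scheme$aa_matrix,
                           scheme$aa_gap_open, scheme$aa_gap_extend, TRUE)
    bits <- bitscore(res$score, scheme, "aa")
    minbit <- bits / pmin(self_bits[pairs$i], self_bits[pairs$j])
    keep <- minbit >= config$minbit
    edges <- data.frame(gene_a = catalogs$gene_id[pairs$i[keep]],
                        gene_b = catalogs$gene_id[pairs$j[keep]],
                        bitscore = bits[keep], minbit = minbit[keep],
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = data.frame(gene_id = catalogs$gene_id,
                                    population_id = catalogs$population_id,
                                    self_bitscore = self_bits,
                                    stringsAsFactors = FALSE),
                 edges = edges),
            class = "similarity_graph")
}

#' Flatten population genomes into a catalog table
#' @param populations named list of \code{population_genome} objects.
#' @return data.frame gene_id, population_id, seq_nt, seq_aa.
#' @export
catalog_table <- function(populations) {
  do.call(rbind, lapply(populations, function(p) {
    data.frame(gene_id = names(p$catalog_nt),
               population_id = p$population_id,
               seq_nt = unname(p$catalog_nt),
               seq_aa = if (is.null(p$catalog_aa)) NA_character_
                        else unname(p$catalog_aa),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Markov clustering of the similarity graph
#'
#' Standard MCL on the minbit-weighted adjacency matrix: self-loops are added
#' with weight equal to the node's maximum incident edge weight (1 for
#' isolated nodes), columns are normalized to a stochastic matrix, and
#' expansion (matrix squaring) alternates with inflation (entrywise power,
#' renormalization) and pruning of entries below \code{mcl_pruning} until the
#' matrix changes by less than \code{mcl_tol} or \code{mcl_max_iter} is
#' reached (non-convergence returns the current clustering with
#' \code{converged = FALSE} and a warning). Clusters are attractor systems;
#' every node is assigned to the system receiving most of its flow (ties to
#' the lowest cluster id), so the output is a partition.
#'
#' @param graph a \code{similarity_graph} (or a symmetric weighted adjacency
#'   matrix with dimnames).
#' @param inflation inflation exponent (> 1), default from config.
#' @param config a \code{\link{threshold_config}} for numerical controls.
#' @return list of class \code{mcl_result}: \code{clusters} (list of gene-id
#'   vectors, largest first), \code{membership} (named integer vector),
#'   \code{converged}, \code{iterations}.
#' @export
mcl_cluster <- function(graph, inflation = config$mcl_inflation,
                        config = threshold_config()) {
  if (inherits(graph, "similarity_graph")) {
    ids <- graph$nodes$gene_id
    A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    if (nrow(graph$edges) > 0) {
      ia <- match(graph$edges$gene_a, ids)
      ib <- match(graph$edges$gene_b, ids)
      A[cbind(ia, ib)] <- graph$edges$minbit
      A[cbind(ib, ia)] <- graph$edges$minbit
    }
  } else {
    A <- as.matrix(graph)
    if (!isSymmetric(unname(A))) stop("adjacency matrix must be symmetric")
    ids <- rownames(A)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(A)))
    diag(A) <- 0
  }
  n <- nrow(A)
  if (n == 0) stop("graph has no nodes")
  loop <- apply(A, 1, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  it <- 0L
  while (it < config$mcl_max_iter) {
    it <- it + 1L
    M2 <- M %*% M
    M2 <- M2^inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    M2[M2 < config$mcl_pruning] <- 0 # prune after rescaling
    cs <- colSums(M2)
    dead <- cs == 0
    if (any(dead)) {
      M2[cbind(which(dead), which(dead))] <- 1
      cs[dead] <- 1
    }
    M2 <- sweep(M2, 2, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < config$mcl_tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge in ", config$mcl_max_iter,
            " iterations; returning current clustering")
  eps <- 1e-6
  attractors <- which(diag(M) > eps)
  if (length(attractors) == 0) attractors <- seq_len(n)
  # attractor systems: attractors connected through shared flow
  sub <- (M[attractors, attractors, drop = FALSE] > eps) |
    t(M[attractors, attractors, drop = FALSE] > eps)
  sys <- components_bool(sub)
  membership <- integer(n)
  flow <- M[attractors, , drop = FALSE]
  for (j in seq_len(n)) {
    f <- tapply(flow[, j], sys, sum)
    if (all(f <= 0)) {
      membership[j] <- NA_integer_
    } else {
      membership[j] <- as.integer(names(f)[which.max(f)])
    }
  }
  # unattached nodes become their own clusters
  if (anyNA(membership)) {
    extra <- max(sys) + seq_len(sum(is.na(membership)))
    membership[is.na(membership)] <- extra
  }
  membership <- as.integer(factor(membership,
                                  levels = unique(membership[order(
                                    membership)])))
  names(membership) <- ids
  cl <- split(ids, membership)
  cl <- cl[order(-vapply(cl, length, integer(1)),
                 vapply(cl, function(x) min(x), character(1)))]
  names(cl) <- sprintf("OG%04d", seq_along(cl))
  membership <- setNames(rep(seq_along(cl), lengths(cl)), unlist(cl))[ids]
  structure(list(clusters = cl, membership = membership,
                 converged = converged, iterations = it),
            class = "mcl_result")
}

# connected components of a logical symmetric matrix (tiny n)
components_bool <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Orthogroup table and presence matrix
#'
#' Joins an MCL clustering with the catalog's population attribution.
#'
#' @param mcl an \code{mcl_result}.
#' @param graph the \code{similarity_graph} the clustering came from.
#' @return list: \code{table} (orthogroup_id, gene_id, population_id),
#'   \code{presence} (orthogroups x populations gene counts).
#' @export
orthogroup_table <- function(mcl, graph) {
  nodes <- graph$nodes
  og <- names(mcl$clusters)[mcl$membership[nodes$gene_id]]
  tab <- data.frame(orthogroup_id = og, gene_id = nodes$gene_id,
                    population_id = nodes$population_id,
                    stringsAsFactors = FALSE)
  pres <- table(factor(tab$orthogroup_id, levels = names(mcl$clusters)),
                tab$population_id)
  pres <- matrix(as.integer(pres), nrow = nrow(pres),
                 dimnames = dimnames(pres))
  list(table = tab, presence = pres)
}

#' Classify orthogroups into frequency classes and order them
#'
#' Classes: \emph{core} (present in every population genome),
#' \emph{singleton} (present in exactly one), \emph{clade-specific} (present
#' in more than one population, all within a single subclade, when a
#' subclade map is supplied) and \emph{shared} (everything else).
#' Orthogroups are ordered by Ward linkage on Euclidean distances between
#' their gene-count frequency vectors. Venn-style sharing counts over an
#' arbitrary grouping of populations (subclades or ecotypes) are returned:
#' for each non-empty combination of groups, the number of orthogroups whose
#' presence spans exactly those groups.
#'
#' @param og result of \code{\link{orthogroup_table}}.
#' @param subclade_map optional data.frame (population_id, group) used for
#'   clade-specific classing and the sharing counts.
#' @return list: \code{classes} (orthogroup_id, n_populations, class),
#'   \code{order} (display order from Ward clustering), \code{sharing}
#'   (data.frame combination, n) when a map is given.
#' @export
classify_orthogroups <- function(og, subclade_map = NULL) {
  pres <- og$presence
  npop <- ncol(pres)
  present <- pres > 0
  count <- rowSums(present)
  cls <- ifelse(count == npop, "core",
                ifelse(count == 1, "singleton", "shared"))
  sharing <- NULL
  if (!is.null(subclade_map)) {
    stopifnot(all(c("population_id", "group") %in% names(subclade_map)))
    missing <- setdiff(colnames(pres), subclade_map$population_id)
    if (length(missing) > 0)
      stop("population absent from subclade map: ",
           paste(missing, collapse = ", "))
    grp <- setNames(subclade_map$group, subclade_map$population_id)
    combos <- apply(present, 1, function(row) {
      paste(sort(unique(grp[colnames(pres)[row]])), collapse = "+")
    })
    one_group <- !grepl("+", combos, fixed = TRUE)
    cls[cls == "shared" & one_group] <- "clade-specific"
    sharing <- as.data.frame(table(combination = combos),
                             stringsAsFactors = FALSE)
    names(sharing)[2] <- "n"
  }
  ord <- if (nrow(pres) > 2) {
    hclust(stats::dist(pres), method = "ward.D2")$order
  } else {
    seq_len(nrow(pres))
  }
  list(classes = data.frame(orthogroup_id = rownames(pres),
                            n_populations = as.integer(count),
                            class = cls, stringsAsFactors = FALSE,
                            row.names = NULL),
       order = rownames(pres)[ord],
       sharing = sharing)
}

#' Population-genome-level ANI from a genome-level matrix
#'
#' ANI between two populations is the mean over all member-genome pairs.
#'
#' @param ani genome-level \code{\link{ani_matrix}}.
#' @param partition data.frame (genome_id, population_id).
#' @return symmetric matrix over populations (diagonal 100).
#' @export
popgenome_ani <- function(ani, partition) {
  pops <- sort(unique(partition$population_id))
  m <- matrix(NA_real_, length(pops), length(pops),
              dimnames = list(pops, pops))
  diag(m) <- 100
  a <- unclass(ani)
  for (i in seq_along(pops)) for (j in seq_len(i - 1)) {
    gi <- partition$genome_id[partition$population_id == pops[i]]
    gj <- partition$genome_id[partition$population_id == pops[j]]
    m[i, j] <- m[j, i] <- mean(a[gi, gj], na.rm = TRUE)
  }
  m[is.nan(m)] <- NA_real_
  m
}

#' Average-linkage (UPGMA) ordering tree from an ANI matrix
#'
#' Hierarchical classification on distance \code{100 - ANI} with average
#' linkage, serialized as a Newick tree whose leaf order defines display
#' order.
#'
#' @param ani symmetric percent-identity matrix with dimnames.
#' @return list: \code{hclust}, \code{phylo} (ape), \code{newick} string,
#'   \code{leaf_order}. For a single leaf the tree is degenerate.
#' @export
order_genomes_by_ani <- function(ani) {
  ids <- rownames(ani)
  if (length(ids) < 2) {
    return(list(hclust = NULL, phylo = NULL,
                newick = paste0(ids, ";"), leaf_order = ids))
  }
  d <- 100 - unclass(ani)
  d[is.na(d)] <- 100
  hc <- hclust(as.dist(d), method = "average")
  ph <- ape::as.phylo(hc)
  list(hclust = hc, phylo = ph,
       newick = ape::write.tree(ph),
       leaf_order = ids[hc$order])
}
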