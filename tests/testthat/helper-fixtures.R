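# Shared fixtures, built once per test session.
.fixtures <- new.env()

# Small community: 2 subclades x 2 genomes, quick to evolve and align.
small_design <- function(seed = 11, reads_per_sample = 1000,
                         completeness_fraction = 1, ...) {
  community_design(n_subclades = 2, genomes_per_subclade = 2,
                   n_core_genes = 6, n_subclade_genes_per_subclade = 2,
                   n_singleton_genes_per_genome = 1,
                   gene_length_mean = 600, gene_length_sd = 60,
                   depth_grid = c(25, 125, 500, 1000),
                   reads_per_sample = reads_per_sample,
                   completeness_fraction = completeness_fraction,
                   contigs_per_genome = 2, rng_seed = seed, ...)
}

get_fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

small_community <- function() {
  get_fixture("small_community", function() evolve_genomes(small_design()))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

random_protein <- function(n, len) {
  aa20 <- setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z"))
  vapply(seq_len(n), function(i)
    paste(sample(aa20, len, replace = TRUE), collapse = ""), character(1))
}

# Planted gene families: n_fam families of size fam_size at the given
# pairwise divergence (half applied per member). Returns named vector with
# family truth in names: "F<fam>_<member>".
planted_families <- function(n_fam, fam_size, len = 600, divergence = 0.02,
                             seed = 5) {
  set.seed(seed)
  out <- character()
  for (f in seq_len(n_fam)) {
    anc <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    for (m in seq_len(fam_size)) {
      s <- metapang:::mutate_seq(anc, round(len * divergence / 2),
                                 coding = FALSE)
      out[sprintf("F%02d_%d", f, m)] <- s
    }
  }
  out
}

family_of <- function(ids) sub("_.*$", "", ids)
truth_family_of_gene <- function(gene_ids) sub("^[^.]+\\.", "", gene_ids)

# connected components of an undirected adjacency matrix (plain BFS)
components_of <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    q <- i
    comp[i] <- cur
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      q <- c(q, nb)
    }
  }
  comp
}
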