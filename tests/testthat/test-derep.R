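test_that("exact duplicates and reverse complements collapse", {
  set.seed(20)
  g <- random_dna(1, 500)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
  other <- random_dna(1, 400)
  cat1 <- dereplicate_genes(c(a = g, b = g, c = other))
  expect_length(cat1$representatives, 2)
  # equal length tie: lexicographically first id represents
  expect_identical(cat1$members$representative_id[
    cat1$members$gene_id == "b"], "a")
  cat2 <- dereplicate_genes(c(fwd = g, rev = rc))
  expect_length(cat2$representatives, 1)
  expect_error(dereplicate_genes(character()), "empty")
})

test_that("greedy catalog equals brute-force components on planted families", {
  genes <- planted_families(12, 5, len = 450, divergence = 0.02, seed = 6)
  cfg <- threshold_config()
  cat <- dereplicate_genes(genes, cfg)
  expect_length(cat$representatives, 12)
  expect_equal(adjusted_rand(cat$members$representative_id,
                             family_of(cat$members$gene_id)), 1)

  # brute force: all-pairs alignment graph at the same thresholds
  sc <- scoring_scheme()
  n <- length(genes)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(genes)))
  adj <- matrix(FALSE, n, n, dimnames = list(names(genes), names(genes)))
  idx <- which(upper.tri(adj), arr.ind = TRUE)
  res_f <- metapang:::cpp_align_pairs(unname(genes), idx[, 1], idx[, 2],
                                      sc$nt_matrix, sc$nt_gap_open,
                                      sc$nt_gap_extend, FALSE)
  res_r <- metapang:::cpp_align_pairs(c(unname(rc), unname(genes)),
                                      idx[, 1], n + idx[, 2],
                                      sc$nt_matrix, sc$nt_gap_open,
                                      sc$nt_gap_extend, FALSE)
  link <- function(res) {
    ident <- ifelse(res$pairs > 0, 100 * res$matches / res$pairs, 0)
    shorter <- pmin(nchar(genes)[idx[, 1]], nchar(genes)[idx[, 2]])
    qspan <- res$qend - res$qstart + 1
    sspan <- res$send - res$sstart + 1
    cov_short <- pmax(qspan, sspan) / shorter
    cov_short <- pmin(cov_short, 1)
    ident >= cfg$derep_identity & cov_short >= cfg$derep_coverage
  }
  hit <- link(res_f) | link(res_r)
  adj[idx[hit, , drop = FALSE]] <- TRUE
  adj <- adj | t(adj)
  diag(adj) <- TRUE
  comp <- components_of(adj)
  expect_equal(adjusted_rand(cat$members$representative_id[
    match(names(genes), cat$members$gene_id)], comp), 1)
})

test_that("catalog order-invariance and the no-residual-pair invariant", {
  genes <- planted_families(8, 4, len = 450, divergence = 0.02, seed = 7)
  cfg <- threshold_config()
  cat1 <- dereplicate_genes(genes, cfg)
  set.seed(1)
  cat2 <- dereplicate_genes(sample(genes), cfg)
  m1 <- setNames(cat1$members$representative_id, cat1$members$gene_id)
  m2 <- setNames(cat2$members$representative_id, cat2$members$gene_id)
  expect_equal(adjusted_rand(m1[names(genes)], m2[names(genes)]), 1)
  # no two representatives still align at >= 95% over >= 90% of the shorter
  reps <- cat1$representatives
  sc <- scoring_scheme()
  for (i in seq_along(reps)) for (j in seq_len(i - 1)) {
    a <- align_nt(reps[i], reps[j], sc)
    short <- min(nchar(reps[i]), nchar(reps[j]))
    cov <- max(a$qend - a$qstart + 1, a$send - a$sstart + 1) / short
    expect_false(a$percent_identity >= cfg$derep_identity &&
                   cov >= cfg$derep_coverage)
  }
})

test_that("population genomes pool and dereplicate member genes", {
  cm <- small_community()
  am <- ani_matrix(cm$genomes)
  part <- cluster_populations(am, "single", 95)
  pops <- build_population_genomes(part, cm$genes)
  # complete genomes: one representative per family present in the subclade
  for (p in pops) {
    fams <- unique(truth_family_of_gene(
      cm$genes$gene_id[cm$genes$genome_id %in% p$members]))
    expect_length(p$catalog_nt, length(fams))
    expect_setequal(truth_family_of_gene(names(p$catalog_nt)), fams)
    # member map sends every gene to a representative of its own family
    expect_identical(truth_family_of_gene(p$member_map$gene_id),
                     truth_family_of_gene(p$member_map$representative_id))
  }
  # orphan gene: partition that does not know the genome
  expect_error(build_population_genomes(part[part$genome_id != "SBg2", ],
                                        cm$genes),
               "SBg2")
  # two identical genomes collapse to one genome's gene count
  twin <- cm$genes[cm$genes$genome_id == "SAg1", ]
  twin2 <- twin
  twin2$genome_id <- "copy"
  twin2$gene_id <- sub("SAg1", "copy", twin2$gene_id)
  both <- rbind(twin, twin2)
  part2 <- data.frame(genome_id = c("SAg1", "copy"),
                      population_id = "P01")
  p2 <- build_population_genomes(part2, both)
  expect_length(p2$P01$catalog_nt, nrow(twin))
})

test_that("populations with zero coverage everywhere are discarded", {
  pops <- list(P01 = structure(list(population_id = "P01"),
                               class = "population_genome"),
               P02 = structure(list(population_id = "P02"),
                               class = "population_genome"))
  cov <- matrix(c(0, 0, 0, 1e-6, 0, 0), nrow = 2, byrow = TRUE,
                dimnames = list(c("P01", "P02"), c("s1", "s2", "s3")))
  kept <- filter_locally_relevant(pops, cov)
  expect_identical(names(kept), "P02") # one read anywhere retains
  expect_identical(attr(kept, "removed"), "P01")
  cov2 <- cov; cov2[1, 1] <- 5
  expect_length(filter_locally_relevant(pops, cov2), 2)
  expect_error(filter_locally_relevant(pops, cov[2, , drop = FALSE]),
               "P01")
})
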