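test_that("minbit keeps strong homologs and drops random proteins", {
  set.seed(30)
  cfg <- threshold_config()
  # identical proteins: minbit 1
  p <- random_protein(1, 120)
  cats <- data.frame(gene_id = c("a", "b"), population_id = c("P1", "P2"),
                     seq_aa = c(p, p), stringsAsFactors = FALSE)
  g <- build_graph(cats, cfg)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$minbit, 1, tolerance = 1e-12)
  # unrelated random length-60 proteins never pass minbit 0.5
  for (i in 1:100) {
    pr <- random_protein(2, 60)
    cats <- data.frame(gene_id = c("a", "b"),
                       population_id = c("P1", "P2"),
                       seq_aa = pr, stringsAsFactors = FALSE)
    gg <- build_graph(cats, cfg, exact = TRUE)
    expect_equal(nrow(gg$edges), 0)
  }
})

test_that("minbit arithmetic follows its definition", {
  # minbit = bits(a,b) / min(selfbits); recompute one real edge by hand
  cm <- small_community()
  a <- cm$genes[cm$genes$gene_id == "SAg1.Fc001", ]
  b <- cm$genes[cm$genes$gene_id == "SBg1.Fc001", ]
  sc <- scoring_scheme()
  cats <- data.frame(gene_id = c(a$gene_id, b$gene_id),
                     population_id = c("P1", "P2"),
                     seq_aa = c(a$seq_aa, b$seq_aa),
                     stringsAsFactors = FALSE)
  g <- build_graph(cats)
  pair_bits <- align_aa(a$seq_aa, b$seq_aa, sc)$bitscore
  self_bits <- bitscore(metapang:::cpp_self_scores(
    c(a$seq_aa, b$seq_aa), sc$aa_matrix, TRUE), sc, "aa")
  expect_equal(g$edges$minbit, pair_bits / min(self_bits))
  # seeded prefilter equals the exhaustive graph on a real catalog
  sub <- cm$genes[cm$genes$genome_id %in% c("SAg1", "SBg1"), ]
  cats2 <- data.frame(gene_id = sub$gene_id,
                      population_id = sub$genome_id,
                      seq_aa = sub$seq_aa, stringsAsFactors = FALSE)
  g1 <- build_graph(cats2)
  g2 <- build_graph(cats2, exact = TRUE)
  expect_equal(g1$edges, g2$edges)
})

test_that("MCL recovers components, isolates and bridged cliques", {
  # two disjoint triangles
  ids <- letters[1:6]
  A <- matrix(0, 6, 6, dimnames = list(ids, ids))
  for (grp in list(1:3, 4:6))
    for (i in grp) for (j in grp) if (i < j) A[i, j] <- A[j, i] <- 1
  r <- mcl_cluster(A, inflation = 10)
  expect_equal(unname(sort(vapply(r$clusters, paste, character(1),
                                  collapse = ""))),
               c("abc", "def"))
  # single isolated node forms its own cluster
  B <- rbind(cbind(A, 0), 0)
  rownames(B)[7] <- colnames(B)[7] <- "g"
  r2 <- mcl_cluster(B, inflation = 10)
  expect_length(r2$clusters, 3)
  expect_true(any(vapply(r2$clusters, identical, logical(1), "g")))
  # two 5-cliques joined by one weak edge split at inflation 10
  ids <- letters[1:10]
  C <- matrix(0, 10, 10, dimnames = list(ids, ids))
  for (grp in list(1:5, 6:10))
    for (i in grp) for (j in grp) if (i < j) C[i, j] <- C[j, i] <- 1
  C[5, 6] <- C[6, 5] <- 0.1
  r3 <- mcl_cluster(C, inflation = 10)
  expect_equal(unname(sort(vapply(r3$clusters, paste, character(1),
                                  collapse = ""))),
               c("abcde", "fghij"))
})

test_that("MCL is a partition agreeing with the dense reference on random graphs", {
  set.seed(31)
  for (case in 1:50) {
    n <- sample(2:6, 1)
    A <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (runif(1) < 0.5) A[i, j] <- A[j, i] <- round(runif(1, 0.1, 1), 2)
    r <- mcl_cluster(A, inflation = 10)
    # partition over all nodes
    expect_setequal(unlist(r$clusters), letters[1:n])
    expect_equal(sum(lengths(r$clusters)), n)
    # no cluster spans two connected components
    adj <- A > 0
    diag(adj) <- TRUE
    comp <- components_of(adj)
    names(comp) <- letters[1:n]
    for (cl in r$clusters)
      expect_length(unique(comp[cl]), 1)
    # agreement with the independent dense implementation
    oracle <- mcl_oracle(A, inflation = 10)
    omem <- setNames(rep(seq_along(oracle), lengths(oracle)),
                     unlist(oracle))
    expect_equal(adjusted_rand(r$membership[letters[1:n]],
                               omem[letters[1:n]]), 1)
  }
})

test_that("MCL equals connected components on uniform-weight cliques", {
  set.seed(32)
  ids <- sprintf("n%02d", 1:12)
  A <- matrix(0, 12, 12, dimnames = list(ids, ids))
  for (grp in list(1:4, 5:6, 7:12))
    for (i in grp) for (j in grp) if (i < j) A[i, j] <- A[j, i] <- 0.8
  r <- mcl_cluster(A, inflation = 10)
  expect_equal(unname(sort(lengths(r$clusters))), c(2L, 4L, 6L))
})

test_that("orthogroup classes and sharing counts follow presence", {
  pres <- rbind(OG1 = c(2, 1, 1, 1), # all populations: core
                OG2 = c(0, 3, 0, 0), # one population: singleton
                OG3 = c(1, 1, 0, 0), # two pops, same subclade
                OG4 = c(1, 0, 1, 0)) # two pops, two subclades
  colnames(pres) <- paste0("P0", 1:4)
  og <- list(presence = pres)
  map <- data.frame(population_id = colnames(pres),
                    group = c("SA", "SA", "SB", "SB"))
  cls <- classify_orthogroups(og, map)
  got <- setNames(cls$classes$class, cls$classes$orthogroup_id)
  expect_identical(unname(got[c("OG1", "OG2", "OG3", "OG4")]),
                   c("core", "singleton", "clade-specific", "shared"))
  sh <- setNames(cls$sharing$n, cls$sharing$combination)
  expect_equal(unname(sh["SA+SB"]), 2) # OG1 and OG4 span both subclades
  expect_equal(unname(sh["SA"]), 2)    # OG2, OG3
  expect_error(classify_orthogroups(og, map[-1, ]), "absent")
})

test_that("orthogroups on complete genomes equal planted orthofamilies", {
  cm <- small_community()
  am <- ani_matrix(cm$genomes)
  part <- cluster_populations(am, "single", 95)
  pops <- build_population_genomes(part, cm$genes)
  g <- build_graph(catalog_table(pops))
  mcl <- mcl_cluster(g)
  og <- orthogroup_table(mcl, g)
  fam <- truth_family_of_gene(og$table$gene_id)
  expect_equal(adjusted_rand(og$table$orthogroup_id, fam), 1)
  cls <- classify_orthogroups(og)
  got <- setNames(cls$classes$class, cls$classes$orthogroup_id)
  fam_of_og <- setNames(fam, og$table$orthogroup_id)
  truth_class <- setNames(cm$truth$family_class$class,
                          cm$truth$family_class$family_id)
  for (o in names(got)) {
    tc <- truth_class[[fam_of_og[[o]]]]
    if (tc == "core") expect_identical(got[[o]], "core")
    if (tc == "singleton") expect_identical(got[[o]], "singleton")
  }
})

test_that("average-linkage ordering tree has the forced topology", {
  m <- matrix(c(100, 90, 80, 90, 100, 80, 80, 80, 100), 3, 3,
              dimnames = list(c("P1", "P2", "P3"), c("P1", "P2", "P3")))
  tr <- order_genomes_by_ani(m)
  expect_match(tr$newick, "P1.*P2|P2.*P1") # P1,P2 sisters
  ph <- tr$phylo
  pair <- ape::extract.clade(ph, ape::getMRCA(ph, c("P1", "P2")))
  expect_setequal(pair$tip.label, c("P1", "P2"))
  # ultrametric input: cophenetic distances reproduce the input
  coph <- ape::cophenetic.phylo(ph)
  expect_equal(coph["P1", "P2"], 10)
  expect_equal(coph["P1", "P3"], 20)
  # single leaf degenerates gracefully
  single <- order_genomes_by_ani(matrix(100, 1, 1,
                                        dimnames = list("P1", "P1")))
  expect_identical(single$newick, "P1;")
})

test_that("tree cut at the 80% subclade boundary recovers planted subclades", {
  cm <- small_community()
  am <- ani_matrix(cm$genomes)
  part <- cluster_populations(am, "single", 95)
  pani <- popgenome_ani(am, part)
  tr <- order_genomes_by_ani(pani)
  cl <- cutree(tr$hclust, h = 100 - 80)
  truth <- setNames(cm$truth$genome_subclade$subclade,
                    cm$truth$genome_subclade$genome_id)
  pop_truth <- vapply(names(cl), function(p)
    unique(truth[part$genome_id[part$population_id == p]]), character(1))
  expect_equal(adjusted_rand(cl, pop_truth), 1)
})
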