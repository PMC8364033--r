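test_that("design invariants are enforced at construction", {
  expect_error(community_design(intra_subclade_divergence = 0.06),
               "intra_subclade_divergence")
  expect_error(community_design(inter_subclade_divergence = 0.04),
               "inter_subclade_divergence")
  expect_error(community_design(intra_subclade_divergence = 0.05,
                                inter_subclade_divergence = 0.051,
                                completeness_fraction = 0),
               "completeness_fraction|ill-posed")
  expect_error(community_design(
    abundance_profiles = data.frame(subclade = c("SA", "SB", "SC", "SD"),
                                    peak_depth = 1:4, width = c(1, 1, -1, 1),
                                    amplitude = 1)),
    "widths positive")
})

test_that("zero intra-subclade divergence yields identical core genes", {
  d <- small_design(seed = 21, intra_subclade_divergence = 0)
  cm <- evolve_genomes(d)
  g <- cm$genes
  core <- g[g$class == "core", ]
  for (fam in unique(core$family_id)) {
    for (sc in c("SA", "SB")) {
      members <- core$seq_nt[core$family_id == fam &
                               startsWith(core$genome_id, sc)]
      expect_length(unique(members), 1)
    }
  }
})

test_that("evolution is deterministic and FASTA output byte-identical", {
  d <- small_design(seed = 33)
  cm1 <- evolve_genomes(d)
  cm2 <- evolve_genomes(d)
  expect_identical(cm1$genomes, cm2$genomes)
  expect_identical(cm1$genes, cm2$genes)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_community(cm1, d1)
  write_community(cm2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})

test_that("planted truth is structurally consistent", {
  cm <- small_community()
  g <- cm$genes
  # every gene in exactly one orthofamily
  expect_false(anyNA(g$family_id))
  expect_false(anyDuplicated(g$gene_id) > 0)
  # core families have one member in every genome (before dropout)
  core <- unique(g$family_id[g$class == "core"])
  for (fam in core)
    expect_setequal(g$genome_id[g$family_id == fam], names(cm$genomes))
  # genes sit where their coordinates claim
  for (i in sample(nrow(g), 20)) {
    contig <- cm$genomes[[g$genome_id[i]]][[g$contig_id[i]]]
    expect_identical(substring(contig, g$start[i], g$end[i]), g$seq_nt[i])
  }
  # proteins are clean translations (no internal stops)
  expect_false(any(grepl("*", g$seq_aa, fixed = TRUE)))
})

test_that("realized pairwise identity tracks the design divergences", {
  cm <- small_community() # intra 0.02, inter 0.25 pairwise targets
  within <- truth_identity(cm, "SAg1", "SAg2")
  across <- truth_identity(cm, "SAg1", "SBg1")
  expect_gt(within, 97)
  expect_lt(within, 99.5)
  expect_lt(across, 80)
  expect_gt(across, 68)
})

test_that("incompleteness drops an exact gene count, reproducibly", {
  cm <- small_community()
  expect_identical(apply_incompleteness(cm, 1), cm)
  deg1 <- apply_incompleteness(cm, 0.5, rng_seed = 9)
  deg2 <- apply_incompleteness(cm, 0.5, rng_seed = 9)
  expect_identical(deg1$genes$gene_id, deg2$genes$gene_id)
  for (gid in names(cm$genomes)) {
    n0 <- sum(cm$genes$genome_id == gid)
    n1 <- sum(deg1$genes$genome_id == gid)
    expect_equal(n1, round(0.5 * n0))
  }
  expect_setequal(c(deg1$genes$gene_id, deg1$truth$dropped),
                  cm$genes$gene_id)
  # retained genes still match their new coordinates
  g <- deg1$genes
  for (i in sample(nrow(g), 10)) {
    contig <- deg1$genomes[[g$genome_id[i]]][[g$contig_id[i]]]
    expect_identical(substring(contig, g$start[i], g$end[i]), g$seq_nt[i])
  }
})

test_that("error-free reads are exact substrings with correct origins", {
  d <- small_design(seed = 41, read_error_rate = 0,
                    reads_per_sample = 200)
  cm <- evolve_genomes(d)
  rs <- sample_reads(cm)
  df <- rs$reads[[1]]
  for (i in sample(nrow(df), 25)) {
    contig <- cm$genomes[[df$genome_id[i]]][[df$contig_id[i]]]
    frag <- substring(contig, df$start[i], df$start[i] + d$read_length - 1)
    if (df$strand[i] == "-")
      frag <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(frag)))
    expect_identical(df$seq[i], frag)
  }
})

test_that("read origins follow the designed abundance mixture", {
  # two subclades at 3:1 amplitude at 25 m, zero abundance for SB at 1000 m
  prof <- data.frame(subclade = c("SA", "SB"), peak_depth = c(25, 25),
                     width = c(30, 30), amplitude = c(3, 1))
  d <- small_design(seed = 55, abundance_profiles = prof,
                    reads_per_sample = 10000)
  # SB confined to the surface (vanishing width), SA broad enough to keep
  # every depth sampled
  prof2 <- prof
  prof2$width <- c(500, 1e-6)
  d2 <- small_design(seed = 56, abundance_profiles = prof2,
                     reads_per_sample = 500)
  cm <- evolve_genomes(d)
  rs <- sample_reads(cm)
  df <- rs$reads[["D0025"]]
  glen <- vapply(cm$genomes, function(g) sum(nchar(g)), numeric(1))
  wA <- 3 * sum(glen[c("SAg1", "SAg2")])
  wB <- 1 * sum(glen[c("SBg1", "SBg2")])
  p <- wA / (wA + wB)
  nA <- sum(startsWith(df$genome_id, "SA"))
  ci <- qbinom(c(0.005, 0.995), nrow(df), p)
  expect_gte(nA, ci[1])
  expect_lte(nA, ci[2])
  # chi-square goodness of fit over genomes is not rejected at alpha 0.01
  w <- glen * ifelse(startsWith(names(glen), "SA"), 3, 1)
  obs <- table(factor(df$genome_id, levels = names(glen)))
  expect_gt(stats::chisq.test(obs, p = w / sum(w))$p.value, 0.01)
  # zero abundance: no reads from SB at any depth away from its spike
  cm2 <- evolve_genomes(d2)
  rs2 <- sample_reads(cm2)
  expect_false(any(startsWith(rs2$reads[["D1000"]]$genome_id, "SB")))
})

test_that("exact-divergence genome mutation reports what it applied", {
  set.seed(7)
  g <- setNames(random_dna(2, 4000), c("c1", "c2"))
  m <- mutate_genome(g, 0.1, rng_seed = 3)
  expect_equal(m$applied_divergence, 0.1, tolerance = 1e-3)
  ch1 <- strsplit(g[["c1"]], "")[[1]]
  ch2 <- strsplit(m$genome[["c1"]], "")[[1]]
  expect_equal(mean(ch1 != ch2), 0.1, tolerance = 1e-3)
})
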