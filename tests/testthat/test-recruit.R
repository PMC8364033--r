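test_that("error-free reads map to their source gene; weak reads are rejected", {
  set.seed(40)
  catalog <- setNames(random_dna(5, 900), paste0("g", 1:5))
  # exact 100-bp substrings are assigned to their source
  reads <- character()
  truth <- character()
  for (g in names(catalog)) {
    st <- sample(1:800, 3)
    reads <- c(reads, substring(catalog[[g]], st, st + 99))
    truth <- c(truth, rep(g, 3))
  }
  names(reads) <- sprintf("r%02d", seq_along(reads))
  asg <- recruit_reads(reads, catalog)
  expect_equal(nrow(asg), length(reads))
  expect_identical(asg$gene_id, truth)
  expect_equal(asg$identity, rep(100, length(reads)))
  # a read at ~75% identity to its best gene fails the 80% threshold
  r75 <- strsplit(substring(catalog[["g1"]], 101, 200), "")[[1]]
  pos <- seq(2, 98, by = 4)[1:25]
  for (p in pos) r75[p] <- setdiff(c("A", "C", "G", "T"), r75[p])[1]
  asg75 <- recruit_reads(c(weak = paste(r75, collapse = "")), catalog,
                         exact = TRUE)
  expect_equal(nrow(asg75), 0)
  expect_equal(attr(asg75, "n_unassigned"), 1)
  # reverse-complement reads recruit on the minus strand
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substring(catalog[["g2"]], 51, 150))))
  asgrc <- recruit_reads(c(rcread = rc), catalog)
  expect_identical(asgrc$gene_id, "g2")
  expect_identical(asgrc$strand, "-")
})

test_that("seeded recruitment equals the exhaustive search on noisy reads", {
  set.seed(41)
  catalog <- setNames(random_dna(8, 700), paste0("g", 1:8))
  reads <- character()
  for (i in 1:120) {
    g <- sample(names(catalog), 1)
    st <- sample(1:600, 1)
    r <- strsplit(substring(catalog[[g]], st, st + 99), "")[[1]]
    nerr <- rbinom(1, 100, 0.02)
    if (nerr > 0) {
      for (p in sample(100, nerr))
        r[p] <- sample(setdiff(c("A", "C", "G", "T"), r[p]), 1)
    }
    reads[sprintf("r%03d", i)] <- paste(r, collapse = "")
  }
  a1 <- recruit_reads(reads, catalog)
  a2 <- recruit_reads(reads, catalog, exact = TRUE)
  expect_identical(a1$read_id, a2$read_id)
  expect_identical(a1$gene_id, a2$gene_id)
  expect_equal(a1$identity, a2$identity)
})

test_that("coverage is aligned bases over gene length, conserved exactly", {
  set.seed(42)
  gene <- setNames(random_dna(1, 1000), "g1")
  # ten tiling reads of 100 bp: mean per-base coverage 1.0
  reads <- setNames(substring(gene, seq(1, 901, by = 100),
                              seq(100, 1000, by = 100)),
                    sprintf("r%02d", 1:10))
  asg <- recruit_reads(reads, gene)
  cov <- coverage_per_gene(list(s1 = asg), gene)
  expect_equal(unname(cov["g1", "s1"]), 1.0)
  # gene with no reads has coverage 0
  two <- c(gene, setNames(random_dna(1, 800), "g2"))
  cov2 <- coverage_per_gene(list(s1 = recruit_reads(reads, two)), two)
  expect_equal(unname(cov2["g2", "s1"]), 0)
  # conservation: total aligned bases equal the sum over accepted reads
  expect_equal(sum(unclass(cov2) * nchar(two)),
               sum(asg$send - asg$sstart + 1))
})

test_that("aggregation means member genes, zeros included", {
  m <- rbind(g1 = c(2, 4), g2 = c(0, 0), g3 = c(1, 2))
  colnames(m) <- c("s1", "s2")
  prof <- structure(m, class = c("coverage_profile", "matrix", "array"))
  agg <- aggregate_coverage(prof, c(g1 = "OG1", g2 = "OG1", g3 = "OG2"))
  expect_equal(unname(agg["OG1", ]), c(1, 2)) # (2+0)/2, (4+0)/2
  expect_equal(unname(agg["OG2", ]), c(1, 2)) # single-gene aggregate
})

test_that("profile scaling is rowwise, zero-safe and idempotent", {
  m <- rbind(a = c(2, 4, 8), b = c(0, 0, 0))
  s <- scale_profiles(m)
  expect_equal(unname(s["a", ]), c(0.25, 0.5, 1))
  expect_equal(unname(s["b", ]), c(0, 0, 0))
  expect_equal(scale_profiles(s), s)
})

test_that("SAM export writes a well-formed minimal dialect", {
  set.seed(43)
  catalog <- setNames(random_dna(2, 300), c("gA", "gB"))
  reads <- setNames(c(substring(catalog[["gA"]], 11, 110),
                      substring(catalog[["gB"]], 51, 150)),
                    c("r1", "r2"))
  asg <- recruit_reads(reads, catalog)
  path <- withr::local_tempfile(fileext = ".sam")
  assignments_to_sam(asg, catalog, path)
  lines <- readLines(path)
  expect_identical(lines[1], "@HD\tVN:1.6\tSO:unsorted")
  expect_length(grep("^@SQ\tSN:g[AB]\tLN:300$", lines), 2)
  aln <- strsplit(grep("^[^@]", lines, value = TRUE), "\t")
  expect_length(aln, 2)
  expect_identical(vapply(aln, `[`, "", 3), c("gA", "gB"))
  expect_identical(vapply(aln, `[`, "", 6), c("100M", "100M"))
})
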