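# handmade population profiles over a depth grid, plus the matching
# average-linkage tree from a block-structured ANI matrix
eco_fixture <- function(profiles, subclade_of, ani_within = 98,
                        ani_between = 75) {
  pops <- rownames(profiles)
  m <- matrix(ani_between, length(pops), length(pops),
              dimnames = list(pops, pops))
  for (sc in unique(subclade_of))
    m[subclade_of == sc, subclade_of == sc] <- ani_within
  diag(m) <- 100
  list(tree = order_genomes_by_ani(m),
       prof = structure(profiles,
                        class = c("coverage_profile", "matrix", "array")))
}

gauss_prof <- function(depths, peak, width, amp = 1) {
  amp * exp(-(depths - peak)^2 / (2 * width^2))
}

test_that("identical profiles merge into one ecotype, disjoint ones stay apart", {
  depths <- c(25, 75, 125, 200, 500, 770, 1000)
  p1 <- gauss_prof(depths, 125, 60)
  prof <- rbind(P01 = p1, P02 = p1)
  colnames(prof) <- depths
  fx <- eco_fixture(prof, c("A", "B"))
  eco <- delineate_ecotypes(fx$tree, fx$prof)
  expect_length(unique(eco$map$ecotype_id), 1)
  # disjoint depth support: correlation <= 0, two ecotypes
  prof2 <- rbind(P01 = c(1, 1, 0, 0, 0, 0, 0),
                 P02 = c(0, 0, 0, 0, 0, 1, 1))
  colnames(prof2) <- depths
  fx2 <- eco_fixture(prof2, c("A", "B"))
  eco2 <- delineate_ecotypes(fx2$tree, fx2$prof)
  expect_length(unique(eco2$map$ecotype_id), 2)
  expect_equal(sort(eco2$map$peak_depth_m), c(25, 770))
  # a leaf without a profile errors by name
  expect_error(delineate_ecotypes(fx2$tree, fx2$prof[1, , drop = FALSE]),
               "P02")
})

test_that("five subclades in four zones give four ecotypes at true peaks", {
  depths <- c(25, 75, 125, 200, 500, 770, 1000)
  prof <- rbind(P01 = gauss_prof(depths, 25, 30),
                P02 = gauss_prof(depths, 125, 50),
                P03 = gauss_prof(depths, 200, 70),
                P04 = gauss_prof(depths, 200, 70, amp = 0.5),
                P05 = gauss_prof(depths, 1000, 250))
  colnames(prof) <- depths
  fx <- eco_fixture(prof, c("A", "B", "C", "D", "E"))
  eco <- delineate_ecotypes(fx$tree, fx$prof)
  expect_length(unique(eco$map$ecotype_id), 4)
  merged <- eco$map$ecotype_id[eco$map$population_id %in% c("P03", "P04")]
  expect_length(unique(merged), 1) # the two same-zone subclades merged
  expect_equal(eco$map$peak_depth_m[match(paste0("P0", 1:5),
                                          eco$map$population_id)],
               c(25, 125, 200, 200, 1000))
})

test_that("delineation ignores per-population coverage rescaling", {
  depths <- c(25, 125, 500, 1000)
  prof <- rbind(P01 = gauss_prof(depths, 25, 50),
                P02 = gauss_prof(depths, 500, 200))
  colnames(prof) <- depths
  fx <- eco_fixture(prof, c("A", "B"))
  eco1 <- delineate_ecotypes(fx$tree, fx$prof)
  prof2 <- prof
  prof2["P01", ] <- prof2["P01", ] * 1000
  prof2["P02", ] <- prof2["P02", ] * 1e-3
  fx2 <- eco_fixture(prof2, c("A", "B"))
  eco2 <- delineate_ecotypes(fx2$tree, fx2$prof)
  expect_identical(eco1$map, eco2$map)
})

test_that("lowering the merge threshold cannot increase the ecotype count", {
  set.seed(50)
  depths <- c(25, 75, 125, 200, 500, 770, 1000)
  prof <- rbind(P01 = gauss_prof(depths, 25, 40),
                P02 = gauss_prof(depths, 100, 60),
                P03 = gauss_prof(depths, 300, 150),
                P04 = gauss_prof(depths, 900, 300))
  colnames(prof) <- depths
  fx <- eco_fixture(prof, c("A", "B", "C", "D"))
  counts <- vapply(c(0.99, 0.9, 0.7, 0.5, 0.2, -1), function(th)
    length(unique(delineate_ecotypes(fx$tree, fx$prof,
                                     merge_corr = th)$map$ecotype_id)),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("pathway profiles average member orthogroups and scale rows", {
  m <- rbind(OG1 = c(4, 2, 0), OG2 = c(0, 2, 4), OG3 = c(1, 1, 1))
  colnames(m) <- c("s1", "s2", "s3")
  prof <- structure(m, class = c("coverage_profile", "matrix", "array"))
  ogt <- data.frame(orthogroup_id = c("OG1", "OG2", "OG3"),
                    gene_id = c("gA", "gB", "gC"))
  ann <- data.frame(gene_id = c("gA", "gB", "gB", "gC", "gZ"),
                    pathway = c("pw1", "pw1", "pw2", "pw2", "pw2"))
  expect_warning(pw <- pathway_profiles(prof, ann, ogt), "unknown")
  # pw1 = mean(OG1, OG2) = (2,2,2) -> scaled all 1
  expect_equal(unname(pw$profiles["pw1", ]), c(1, 1, 1))
  # orthogroup OG2 feeds both pathways (many-to-many annotation)
  expect_true(all(c("pw1", "pw2") %in% names(pw$members)))
  # single-orthogroup pathway equals that orthogroup's scaled profile
  ann1 <- data.frame(gene_id = "gA", pathway = "solo")
  pw1 <- pathway_profiles(prof, ann1, ogt)
  expect_equal(unname(pw1$profiles["solo", ]),
               unname(scale_profiles(m)["OG1", ]))
})

test_that("pathway clustering recovers planted depth regimes", {
  set.seed(51)
  depths <- c(25, 75, 125, 200, 500, 770, 1000)
  regimes <- list(surface = c(25, 40), mid = c(200, 80),
                  deep = c(900, 250))
  prof <- t(vapply(rep(seq_along(regimes), each = 4), function(k) {
    base <- gauss_prof(depths, regimes[[k]][1], regimes[[k]][2])
    pmax(0, base + rnorm(length(depths), 0, 0.03))
  }, numeric(length(depths))))
  rownames(prof) <- sprintf("pw%02d", 1:12)
  colnames(prof) <- depths
  truth <- rep(1:3, each = 4)
  cl <- cluster_pathway_profiles(scale_profiles(prof), k = 3)
  expect_equal(adjusted_rand(cl$clusters$cluster, truth), 1)
  # labels ordered shallow-first
  expect_identical(cl$clusters$cluster[1], 1L)
  expect_identical(cl$clusters$cluster[12], 3L)
  # identical profiles land in one cluster at any cut
  two <- prof[c(1, 1, 5, 9), ]
  rownames(two) <- paste0("q", 1:4)
  cl2 <- cluster_pathway_profiles(scale_profiles(two), k = 3)
  expect_identical(cl2$clusters$cluster[1], cl2$clusters$cluster[2])
  # order invariance
  perm <- sample(nrow(prof))
  clp <- cluster_pathway_profiles(scale_profiles(prof)[perm, ], k = 3)
  reord <- clp$clusters$cluster[match(cl$clusters$pathway,
                                      clp$clusters$pathway)]
  expect_equal(adjusted_rand(reord, cl$clusters$cluster), 1)
})
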