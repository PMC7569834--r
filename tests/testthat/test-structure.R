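test_that("allele-sharing distance counts per-site allele differences", {
  g <- toy_panel(rbind(c(0L, 2L, 1L), c(0L, 2L, 1L)))
  expect_equal(unname(pairwise_distance(g)[1, 2]), 0)

  g2 <- toy_panel(rbind(rep(0L, 5), rep(2L, 5)))
  expect_equal(unname(pairwise_distance(g2)[1, 2]), 1)

  g3 <- toy_panel(rbind(c(0L, 2L, 1L), c(0L, 0L, 1L)))
  expect_equal(unname(pairwise_distance(g3)[1, 2]), 1 / 3)

  # missing pairs excluded from the denominator
  g4 <- toy_panel(rbind(c(0L, NA, 2L), c(0L, 2L, 0L)))
  expect_equal(unname(pairwise_distance(g4)[1, 2]), 1 / 2)

  g5 <- toy_panel(rbind(c(0L, NA), c(NA, 2L)))
  expect_error(pairwise_distance(g5), "no called site")
})

test_that("3-taxon NJ solves the three-point equations exactly", {
  d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  co <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(co, d)
})

test_that("NJ recovers additive trees exactly, up to 8 taxa", {
  # the documented 4-taxon case ((A:1,B:2):1.5,(C:1,D:3))
  d4 <- as.matrix(read.delim(file.path(fixture_dir(), "additive_distances.tsv"),
                             row.names = 1))
  colnames(d4) <- rownames(d4)
  tr <- neighbor_joining(d4)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d4), colnames(d4)], d4)
  expect_true(all(tr$edge.length >= 0))

  set.seed(909)
  for (n in 4:8) {
    ref <- ape::rtree(n, rooted = FALSE)
    ref$edge.length <- runif(nrow(ref$edge), 0.1, 2)
    dmat <- ape::cophenetic.phylo(ref)
    got <- neighbor_joining(dmat)
    expect_equal(ape::cophenetic.phylo(got)[rownames(dmat), colnames(dmat)],
                 dmat, tolerance = 1e-10)
  }
})

test_that("negative NJ branches are clamped with the deficit transferred", {
  # a near-degenerate matrix that drives an NJ edge negative
  d <- matrix(c(
    0, 5, 9, 9,
    5, 0, 8, 8,
    9, 8, 0, 1,
    9, 8, 1, 0
  ), 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- 0.1
  d["B", "A"] <- 0.1
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))

  dbad <- d
  dbad[1, 2] <- 7
  expect_error(neighbor_joining(dbad), "symmetric")
  expect_error(neighbor_joining(d[1:2, 1:2]), ">= 3")
})

test_that("bootstrap supports are reproducible and bounded", {
  sim <- suppressMessages(simulate_genotypes(sim_config(
    seed = 21, n_landrace = 6, n_ppb = 6, n_admixed = 0,
    n_chrom = 2, n_snps = 300, base_fst = 0.25,
    planted_regions = NULL, planted_outliers = NULL,
    maf_floor_fraction = 0
  )))
  g <- sim$genotypes
  t1 <- bootstrap_support(g, replicates = 50, seed = 5)
  t2 <- bootstrap_support(g, replicates = 50, seed = 5)
  expect_identical(attr(t1, "support"), attr(t2, "support"))
  s <- attr(t1, "support")
  expect_true(all(s[!is.na(s)] >= 0 & s[!is.na(s)] <= 1))

  one <- bootstrap_support(g, replicates = 1, seed = 9)
  s1 <- attr(one, "support")
  expect_true(all(s1[!is.na(s1)] %in% c(0, 1)))

  # strongly diverged subpopulations: the separating bipartition is certain
  lr <- sim$map$sample_id[sim$map$group == "LANDRACE"]
  parts <- ape::prop.part(t1)
  labs <- attr(parts, "labels")
  grp_split <- vapply(parts, function(p) {
    setequal(labs[p], lr) || setequal(labs[-p], lr)
  }, logical(1))
  expect_true(any(grp_split))
  expect_gte(max(s[grp_split], na.rm = TRUE), 0.95)
})

test_that("two diverged subpopulations form two clades in the NJ tree", {
  sim <- suppressMessages(simulate_genotypes(sim_config(
    seed = 33, n_landrace = 8, n_ppb = 8, n_admixed = 0,
    n_chrom = 2, n_snps = 400, base_fst = 0.3,
    planted_regions = NULL, planted_outliers = NULL, maf_floor_fraction = 0
  )))
  tr <- neighbor_joining(pairwise_distance(sim$genotypes))
  lr <- sim$map$sample_id[sim$map$group == "LANDRACE"]
  parts <- ape::prop.part(tr)
  labs <- attr(parts, "labels")
  expect_true(any(vapply(parts, function(p) {
    setequal(labs[p], lr) || setequal(labs[-p], lr)
  }, logical(1))))
})

test_that("genotype PCA separates diverged groups and is order-invariant", {
  sim <- suppressMessages(simulate_genotypes(sim_config(
    seed = 44, n_landrace = 10, n_ppb = 10, n_admixed = 0,
    n_chrom = 2, n_snps = 400, base_fst = 0.2,
    planted_regions = NULL, planted_outliers = NULL, maf_floor_fraction = 0
  )))
  g <- suppressMessages(impute_missing(sim$genotypes))
  pca <- genotype_pca(g)
  sc <- dplyr::left_join(pca$scores, sim$map, by = "sample_id")
  a <- sc$PC1[sc$group == "LANDRACE"]
  b <- sc$PC1[sc$group == "PPB"]
  expect_true(max(min(a), min(b)) > min(max(a), max(b))) # disjoint PC1 ranges

  expect_equal(sum(pca$var_explained), 1, tolerance = 1e-10)
  expect_true(all(diff(pca$var_explained) <= 1e-12))

  perm <- sample(g$sample_ids)
  pca2 <- genotype_pca(subset_samples(g, perm))
  m <- dplyr::inner_join(pca$scores, pca2$scores, by = "sample_id")
  expect_equal(abs(cor(m$PC1.x, m$PC1.y)), 1, tolerance = 1e-8)

  dup <- toy_panel(rbind(c(0L, 2L, 0L, 2L), c(0L, 2L, 0L, 2L), c(2L, 0L, 2L, 0L),
                         c(1L, 1L, 0L, 2L)))
  p3 <- genotype_pca(dup)
  expect_equal(p3$scores$PC1[1], p3$scores$PC1[2], tolerance = 1e-10)
})

test_that("trees serialise to newick with supports as node labels", {
  g <- toy_panel(matrix(sample(c(0L, 2L), 5 * 30, TRUE), 5, 30))
  tr <- bootstrap_support(g, replicates = 10, seed = 2)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- ape::read.tree(f)
  expect_setequal(back$tip.label, g$sample_ids)
  expect_false(is.null(back$node.label))
})
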