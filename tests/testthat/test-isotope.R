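test_that("B value estimation is the mean of N-free records", {
  expect_equal(estimate_b_value(c(-1.8, -2.2)), -2.0)
  expect_equal(estimate_b_value(-1.5), -1.5)
  expect_error(estimate_b_value(numeric(0)), "no records")
  set.seed(1)
  x <- rnorm(20, mean = -2, sd = 0.4)
  expect_lt(abs(estimate_b_value(x) - (-2)), 2 * 0.4 / sqrt(20))
})

test_that("percent_ndfa reproduces the defining cases and stays unclamped", {
  expect_equal(percent_ndfa(3, 3, -2), 0)     # fixing plant = reference
  expect_equal(percent_ndfa(3, -2, -2), 100)  # fixing plant = B
  expect_equal(percent_ndfa(4, 1, -2), 50)
  expect_equal(percent_ndfa(3, 4, -2), -20)   # negative passes through
  expect_error(percent_ndfa(3, 1, 3), "denominator")
})

test_that("percent_ndfa is invariant to a common shift of ref, fix and B", {
  set.seed(2)
  for (i in 1:20) {
    ref <- runif(1, 1, 5)
    fix <- runif(1, -2, ref)
    b <- runif(1, -4, 0)
    shift <- runif(1, -10, 10)
    expect_equal(percent_ndfa(ref, fix, b),
                 percent_ndfa(ref + shift, fix + shift, b + shift),
                 tolerance = 1e-10)
  }
})

test_that("carbon discrimination matches the worked example and decreases in delta13C", {
  expect_equal(carbon_discrimination(-28.2), 0.0202 / 0.9718 * 1000,
               tolerance = 1e-12)
  expect_lt(abs(carbon_discrimination(-28.2) - 20.79), 0.01)
  expect_equal(carbon_discrimination(-8), 0)
  expect_equal(carbon_discrimination(-18), 0.010 / 0.982 * 1000,
               tolerance = 1e-12)
  x <- seq(-35, -10, by = 0.5)
  expect_true(all(diff(carbon_discrimination(x)) < 0))
})

test_that("ndfa_table anchors on the per-environment reference mean", {
  rec <- tibble::tibble(
    genotype_id = c("R99", "R99", "HON34"),
    group = c("CHECK", "CHECK", "LANDRACE"),
    environment = "YORITO", plot = c(1, 2, 1),
    delta15N = c(2.5, 3.5, 1.5), delta13C = -28.2,
    is_reference = c(TRUE, TRUE, FALSE)
  )
  out <- ndfa_table(rec, isotope_config(b = -2))
  expect_equal(unique(out$delta15n_ref), 3.0)
  expect_equal(out$ndfa_percent[out$genotype_id == "HON34"], 30.0)
  expect_true(is.na(out$ndfa_percent[1]))
  expect_false(any(out$out_of_range))
  expect_equal(unique(out$delta_cap_13c), carbon_discrimination(-28.2))

  noref <- dplyr::mutate(rec, is_reference = FALSE)
  expect_error(ndfa_table(noref, isotope_config(b = -2)), "YORITO")
  expect_error(ndfa_table(rec, isotope_config(b = 5)), "exceed B")

  hot <- dplyr::mutate(rec, delta15N = ifelse(is_reference, delta15N, 4.5))
  expect_true(any(ndfa_table(hot, isotope_config(b = -2))$out_of_range))
})

test_that("isotope fixtures read back and carry the worked-example row", {
  tab <- read_isotope_table(file.path(fixture_dir(), "isotopes.tsv"))
  expect_true(any(tab$delta13C == -28.2))
  out <- ndfa_table(tab, isotope_config(b = -2))
  expect_equal(out$ndfa_percent[out$genotype_id == "HON34"], 30.0)
})

test_that("pearson_matrix uses pairwise-complete cells with a pair floor", {
  set.seed(3)
  t1 <- tibble::tibble(g = letters[1:20], x = rnorm(20))
  t1$y <- -2 * t1$x
  t1$z <- rnorm(20)
  r <- pearson_matrix(t1)
  expect_equal(diag(r), c(x = 1, y = 1, z = 1))
  expect_equal(r["x", "y"], -1)
  expect_equal(r, t(r))

  m <- matrix(rnorm(100), 20, 5, dimnames = list(NULL, paste0("t", 1:5)))
  m[sample(100, 10)] <- NA
  r2 <- pearson_matrix(tibble::as_tibble(m))
  want <- cor(m, use = "pairwise.complete.obs")
  expect_equal(unclass(r2), unclass(want), tolerance = 1e-12)

  sparse <- tibble::tibble(a = c(1, 2, NA, NA, 5), b = c(NA, NA, 3, 4, NA))
  r3 <- pearson_matrix(tibble::tibble(sparse, c = rnorm(5)), min_pairs = 3)
  expect_true(is.na(r3["a", "b"]))
})

test_that("gt_biplot geometry mirrors trait correlations", {
  set.seed(4)
  base <- rnorm(30)
  tab <- tibble::tibble(
    genotype_id = sprintf("g%02d", 1:30),
    t1 = base, t2 = base,            # identical traits
    t3 = -base + rnorm(30, sd = 1e-8) # anticorrelated
  )
  bp <- gt_biplot(tab)
  l <- as.matrix(bp$loadings[, c("PC1", "PC2")])
  cosang <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  expect_equal(cosang(l[1, ], l[2, ]), 1, tolerance = 1e-6)   # angle 0
  expect_equal(cosang(l[1, ], l[3, ]), -1, tolerance = 1e-6)  # angle pi

  tab2 <- tibble::tibble(genotype_id = sprintf("g%02d", 1:25),
                         a = rnorm(25), b = rnorm(25), c = rnorm(25),
                         d = rnorm(25))
  bp2 <- gt_biplot(tab2, n_components = 4)
  sc <- as.matrix(bp2$scores[, -1])
  off <- crossprod(sc)
  expect_true(all(abs(off[upper.tri(off)]) < 1e-10)) # orthogonal scores
  expect_true(all(diff(bp2$var_explained) <= 1e-12))
  expect_lte(sum(bp2$var_explained), 1 + 1e-12)

  # with two dominant latent factors, PC1/PC2 loading angles reproduce the
  # correlation signs of every strongly correlated trait pair
  u <- rnorm(40)
  v <- rnorm(40)
  tab3 <- tibble::tibble(
    genotype_id = sprintf("g%02d", 1:40),
    a = u + rnorm(40, sd = 0.2), b = u + rnorm(40, sd = 0.2),
    c = v + rnorm(40, sd = 0.2), d = -v + rnorm(40, sd = 0.2)
  )
  bp3 <- gt_biplot(tab3)
  r <- pearson_matrix(tab3)
  l3 <- as.matrix(bp3$loadings[, -1])
  rownames(l3) <- bp3$loadings$trait
  for (pair in list(c("a", "b"), c("c", "d"))) {
    expect_equal(sign(sum(l3[pair[1], ] * l3[pair[2], ])),
                 sign(r[pair[1], pair[2]]))
  }

  expect_error(gt_biplot(tab2[1:2, ]), ">= 3")
  expect_message(
    gt_biplot(dplyr::mutate(tab2, a = ifelse(dplyr::row_number() == 1, NA, a))),
    "dropped 1"
  )
})

test_that("tidy and glance summarise biplot objects", {
  set.seed(5)
  tab <- tibble::tibble(genotype_id = sprintf("g%02d", 1:10),
                        a = rnorm(10), b = rnorm(10))
  bp <- gt_biplot(tab)
  td <- tidy(bp)
  expect_setequal(unique(td$kind), c("score", "loading"))
  gl <- glance(bp)
  expect_equal(gl$n_genotypes, 10L)
  expect_equal(gl$n_traits, 2L)
})
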