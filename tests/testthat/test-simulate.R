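small_cfg <- function(seed = 1, ...) {
  defaults <- list(
    seed = seed, n_landrace = 10, n_ppb = 10, n_admixed = 4,
    n_chrom = 3, n_snps = 900,
    planted_regions = tibble::tibble(
      chrom = "Pv01", start = 2e6, end = 3e6, multiplier = 5
    ),
    planted_outliers = tibble::tibble(
      chrom = "Pv02", pos = 1e6, delta = 0.9
    )
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("the generator is byte-deterministic under its seed", {
  s1 <- simulate_genotypes(small_cfg(seed = 5))
  s2 <- simulate_genotypes(small_cfg(seed = 5))
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(s1$genotypes, f1)
  write_vcf(s2$genotypes, f2)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- simulate_genotypes(small_cfg(seed = 6))
  expect_false(identical(s1$genotypes$dosage, s3$genotypes$dosage))
})

test_that("full inbreeding yields no heterozygous calls", {
  sim <- simulate_genotypes(small_cfg(seed = 2, inbreeding = 1,
                                      missing_rate = 0, maf_floor_fraction = 0))
  expect_false(any(sim$genotypes$dosage == 1L, na.rm = TRUE))
})

test_that("a fully fixed planted difference gives F_ST = 1 downstream", {
  cfg <- small_cfg(seed = 3, inbreeding = 1, missing_rate = 0,
                   planted_outliers = tibble::tibble(
                     chrom = "Pv02", pos = 1e6, delta = 1
                   ))
  sim <- simulate_genotypes(cfg)
  fst <- suppressMessages(
    windowed_fst(sim$genotypes, sim$map, "LANDRACE", "PPB")
  )
  at <- fst[fst$chrom == "Pv02" &
              fst$pos == sim$truth$planted_outliers$realized_pos, ]
  expect_equal(at$fst_weighted, 1)
})

test_that("the default panel filters to the published site count", {
  sim <- suppressMessages(simulate_genotypes(sim_config(seed = 9)))
  expect_equal(n_sites(sim$genotypes), 5398)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$genotypes, f)
  g <- suppressMessages(read_vcf(f, min_maf = 0.01, max_missing = 0.2))
  expect_equal(n_sites(g), 4314) # 1084 planted below the MAF floor
  expect_equal(sum(sim$truth$floor_site), 1084)
  expect_equal(length(sim$map$sample_id), 72)
})

test_that("realized MAF respects the planted floor split", {
  sim <- suppressMessages(simulate_genotypes(small_cfg(seed = 4)))
  maf <- allele_summary(sim$genotypes)$maf
  fl <- sim$truth$floor_site
  expect_true(all(maf[fl] <= 0.01))
  expect_true(all(maf[!fl] > 0.01))
})

test_that("infeasible region multipliers are rejected by name", {
  cfg <- small_cfg(seed = 1)
  cfg$planted_regions$multiplier <- 12 # requires heterozygosity > 0.5
  expect_error(simulate_genotypes(cfg), "infeasible multiplier")
})

test_that("realized planted-region diversity ratio tracks the multiplier", {
  ratios <- vapply(1:10, function(s) {
    sim <- suppressMessages(simulate_genotypes(small_cfg(
      seed = s, n_landrace = 30, n_ppb = 30, n_admixed = 0
    )))
    gi <- suppressMessages(impute_missing(filter_sites(sim$genotypes)))
    lr <- sim$map$sample_id[sim$map$group == "LANDRACE"]
    pp <- sim$map$sample_id[sim$map$group == "PPB"]
    wa <- windowed_pi(gi, lr)
    wb <- windowed_pi(gi, pp)
    tr <- sim$truth$planted_regions
    ia <- wa$chrom == tr$chrom & wa$start == tr$start
    ib <- wb$chrom == tr$chrom & wb$start == tr$start
    wa$pi[ia] / wb$pi[ib]
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 5) / 5, 0.2)
})

test_that("isotope simulation inverts exactly at zero noise", {
  map <- tibble::tibble(
    sample_id = sprintf("g%02d", 1:20),
    group = rep(c("LANDRACE", "PPB"), each = 10),
    is_reference = FALSE
  )
  iso <- simulate_isotopes(map, noise_sd = 0, seed = 8)
  tab <- ndfa_table(iso$records, isotope_config(b = -2))
  est <- dplyr::summarise(dplyr::filter(tab, !is_reference),
                          ndfa = mean(ndfa_percent), dc = mean(delta_cap_13c),
                          .by = genotype_id)
  truth <- iso$truth$genotypes
  m <- dplyr::inner_join(est, truth, by = "genotype_id")
  expect_equal(m$ndfa, m$true_ndfa, tolerance = 1e-12)
  expect_equal(m$dc, m$true_dc13, tolerance = 1e-12)
})

test_that("a true discrimination of 20.79 permil maps back to -28.2 delta13C", {
  map <- tibble::tibble(sample_id = "g1", group = "LANDRACE",
                        is_reference = FALSE)
  want <- carbon_discrimination(-28.2) # 20.786...
  iso <- simulate_isotopes(map, noise_sd = 0, dc13_mean = want, dc13_sd = 0,
                           n_plots = 1, seed = 1)
  got <- iso$records$delta13C[!iso$records$is_reference]
  expect_equal(got, -28.2, tolerance = 1e-10)
})

test_that("group %Ndfa contrast powers a significant Welch difference in most seeds", {
  map <- tibble::tibble(
    sample_id = sprintf("g%02d", 1:44),
    group = rep(c("LANDRACE", "PPB"), each = 22),
    is_reference = FALSE
  )
  p <- vapply(1:10, function(s) {
    iso <- simulate_isotopes(map, seed = s)
    tab <- ndfa_table(iso$records, isotope_config(b = -2))
    est <- dplyr::summarise(dplyr::filter(tab, !is_reference),
                            ndfa = mean(ndfa_percent),
                            .by = c(genotype_id, group))
    welch_t_test(est$ndfa[est$group == "LANDRACE"],
                 est$ndfa[est$group == "PPB"])$p_value
  }, numeric(1))
  expect_gte(sum(p < 0.05), 7)
})

test_that("fixtures are deterministic and documented", {
  d1 <- file.path(tempdir(), "fx1")
  d2 <- file.path(tempdir(), "fx2")
  make_fixture_suite(d1)
  make_fixture_suite(d1) # overwrite in place
  make_fixture_suite(d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  g <- read_vcf(file.path(d1, "toy.vcf"), min_maf = 0, max_missing = 1)
  expect_equal(n_sites(g), 4)
  iso <- read_isotope_table(file.path(d1, "isotopes.tsv"))
  expect_true(any(iso$delta13C == -28.2))
})
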