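#' Configuration for the synthetic SNP-panel generator
#'
#' Defaults emulate the study panel the pipeline targets: a 6K bean array
#' yielding 5398 assayed SNPs on 11 chromosomes of ~50 Mbp, 72 inbred lines
#' in two breeding-history subpopulations (landrace, PPB) with an admixed
#' set, near-zero heterozygosity (predominantly self-pollinating species),
#' ~20% of assay sites below the MAF 0.01 panel filter, and planted
#' contrasts with known truth: regions where landrace diversity exceeds PPB
#' diversity by a stated multiplier, and individual sites with a planted
#' between-group frequency gap.
#'
#' @param n_landrace,n_ppb,n_admixed Samples per subpopulation (30/30/12 by
#'   default, 72 lines total).
#' @param admixture Admixed individuals draw allele frequencies from
#'   `admixture * p_landrace + (1 - admixture) * p_ppb`.
#' @param n_chrom Number of chromosomes (default 11).
#' @param chrom_length Chromosome length in bp (default 5e7).
#' @param n_snps Total assayed SNP count before MAF filtering (default 5398).
#' @param freq_shape Shape of the symmetric Beta baseline allele-frequency
#'   law (default 0.8).
#' @param base_fst Balding-Nichols drift parameter separating the two
#'   subpopulations at background sites (default 0.02: mild structure that
#'   separates groups in PCA without faking selection signals; the study
#'   groups are two domesticated gene-pool subsets, not wild vs cultivated).
#' @param inbreeding Within-line inbreeding coefficient F (default 0.98;
#'   heterozygous calls are rare).
#' @param planted_regions Tibble `chrom`, `start`, `end` (0-based half-open),
#'   `multiplier` (> 1): regions where expected landrace heterozygosity is
#'   `multiplier` times PPB heterozygosity. Default: five 1 Mb regions with
#'   multiplier 5, the typical per-window contrast the diversity-ratio scan
#'   is meant to recover.
#' @param planted_outliers Tibble `chrom`, `pos`, `delta`: sites with
#'   `|p_landrace - p_ppb| = delta` (default six sites with delta 0.9).
#' @param region_het Range of PPB (group B) expected heterozygosity inside
#'   planted regions; landrace heterozygosity is `multiplier` times a draw
#'   from this range.
#' @param region_min_snps Minimum SNPs guaranteed inside each planted region
#'   so a windowed contrast is estimable.
#' @param freq_range Truncation of baseline/subpopulation allele
#'   frequencies, reflecting the intermediate-frequency ascertainment of
#'   array SNPs.
#' @param missing_rate Per-call missing probability (default 0.02; the
#'   source panels report < 3%).
#' @param maf_floor_fraction Fraction of assay sites simulated at MAF at or
#'   below 0.01 (default 1084/5398, so the default panel filters to 4314
#'   polymorphic SNPs).
#' @param seed Integer seed; all generator randomness flows through it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_landrace = 30, n_ppb = 30, n_admixed = 12,
                       admixture = 0.5,
                       n_chrom = 11, chrom_length = 5e7, n_snps = 5398,
                       freq_shape = 0.8, base_fst = 0.02, inbreeding = 0.98,
                       planted_regions = default_planted_regions(),
                       planted_outliers = default_planted_outliers(),
                       region_het = c(0.05, 0.09),
                       region_min_snps = 10,
                       freq_range = c(0.1, 0.9),
                       missing_rate = 0.02,
                       maf_floor_fraction = 1084 / 5398,
                       seed = 1) {
  cfg <- list(
    n_landrace = n_landrace, n_ppb = n_ppb, n_admixed = n_admixed,
    admixture = admixture, n_chrom = n_chrom, chrom_length = chrom_length,
    n_snps = n_snps, freq_shape = freq_shape, base_fst = base_fst,
    inbreeding = inbreeding,
    region_het = region_het, region_min_snps = as.integer(region_min_snps),
    freq_range = freq_range,
    planted_regions = if (is.null(planted_regions)) NULL else as_tibble(planted_regions),
    planted_outliers = if (is.null(planted_outliers)) NULL else as_tibble(planted_outliers),
    missing_rate = missing_rate, maf_floor_fraction = maf_floor_fraction,
    seed = as.integer(seed)
  )
  if (!is.null(cfg$planted_regions) && nrow(cfg$planted_regions) > 0 &&
      any(cfg$planted_regions$multiplier <= 1)) {
    abort("sim_config: planted region multipliers must exceed 1")
  }
  if (!is.null(cfg$planted_outliers) && nrow(cfg$planted_outliers) > 0 &&
      any(cfg$planted_outliers$delta < 0 | cfg$planted_outliers$delta > 1)) {
    abort("sim_config: planted outlier deltas must lie in [0, 1]")
  }
  if (cfg$inbreeding < 0 || cfg$inbreeding > 1) {
    abort("sim_config: inbreeding must lie in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_planted_regions <- function() {
  tibble(
    chrom = sim_chrom_name(c(1, 3, 5, 8, 11)),
    start = c(23, 10, 25, 40, 45) * 1e6,
    end = c(24, 11, 26, 41, 46) * 1e6,
    multiplier = 5
  )
}

#' @rdname sim_config
#' @export
default_planted_outliers <- function() {
  tibble(
    chrom = sim_chrom_name(c(2, 7, 7, 9, 9, 11)),
    pos = c(48.9, 0.6, 38.9, 5.5, 7.8, 52.4) * 1e6,
    delta = 0.9
  )
}

sim_chrom_name <- function(i) sprintf("Pv%02d", i)

#' Simulate a structured SNP panel with known truth
#'
#' Per site an ancestral frequency is drawn from the baseline Beta law and
#' subpopulation frequencies are perturbed Balding-Nichols style around it.
#' Planted regions override landrace/PPB frequencies so expected landrace
#' heterozygosity is the configured multiple of PPB heterozygosity; planted
#' outlier sites fix the configured frequency gap (centred on 0.5).
#' Genotypes are drawn with inbreeding F (a line is `2 x Bernoulli(p)` with
#' probability F, else `Binomial(2, p)`); admixed lines mix the two
#' subpopulation frequencies. A configured fraction of sites is emitted at
#' panel MAF at or below 0.01 (all-reference or a single heterozygote), and
#' the remaining sites are guaranteed a post-missingness panel MAF above
#' 0.01, so the MAF filter removes exactly the planted floor sites.
#' Deterministic under `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list: `genotypes` (a [genotype_matrix()]), `map` (population
#'   map tibble; groups `LANDRACE`, `PPB`, `ADMIXED`), and `truth` (list
#'   with per-site group frequencies, the planted region/outlier tables with
#'   realised site positions, and the seed).
#' @export
simulate_genotypes <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chroms <- sim_chrom_name(seq_len(cfg$n_chrom))
  per_chrom <- rep(cfg$n_snps %/% cfg$n_chrom, cfg$n_chrom)
  extra <- cfg$n_snps %% cfg$n_chrom
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L

  sites <- dplyr::bind_rows(purrr::map2(chroms, per_chrom, function(ch, k) {
    tibble(chrom = ch, pos = sort(sample.int(cfg$chrom_length, k)))
  }))

  # guarantee each planted region holds enough SNPs for a windowed contrast
  regions <- cfg$planted_regions
  if (!is.null(regions) && nrow(regions) > 0) {
    for (i in seq_len(nrow(regions))) {
      on_chrom <- which(sites$chrom == regions$chrom[i])
      if (!length(on_chrom)) abort(paste0("no chromosome ", regions$chrom[i]))
      inside <- on_chrom[sites$pos[on_chrom] > regions$start[i] &
                           sites$pos[on_chrom] <= regions$end[i]]
      need <- cfg$region_min_snps - length(inside)
      if (need > 0) {
        pool <- setdiff(on_chrom, inside)
        donors <- pool[sample.int(length(pool), need)]
        taken <- sites$pos[inside]
        fresh <- integer(0)
        while (length(fresh) < need) {
          cand <- regions$start[i] +
            sample.int(regions$end[i] - regions$start[i], need - length(fresh))
          fresh <- unique(c(fresh, setdiff(cand, taken)))
        }
        sites$pos[donors] <- sort(fresh[seq_len(need)])
      }
    }
    sites <- dplyr::arrange(sites, .data$chrom, .data$pos)
  }
  L <- nrow(sites)

  # site roles: planted outliers snap to the nearest simulated site
  region_site <- rep(0L, L)
  if (!is.null(regions) && nrow(regions) > 0) {
    for (i in seq_len(nrow(regions))) {
      hit <- sites$chrom == regions$chrom[i] &
        sites$pos > regions$start[i] & sites$pos <= regions$end[i]
      region_site[hit] <- i
    }
  }
  outliers <- cfg$planted_outliers
  outlier_site <- rep(0L, L)
  if (!is.null(outliers) && nrow(outliers) > 0) {
    outliers$realized_pos <- NA_integer_
    for (i in seq_len(nrow(outliers))) {
      cand <- which(sites$chrom == outliers$chrom[i] & region_site == 0L &
                      outlier_site == 0L)
      if (!length(cand)) abort(paste0("no free site on ", outliers$chrom[i]))
      pick <- cand[which.min(abs(sites$pos[cand] - outliers$pos[i]))]
      outlier_site[pick] <- i
      outliers$realized_pos[i] <- sites$pos[pick]
    }
  }
  n_floor <- round(cfg$maf_floor_fraction * L)
  free <- which(region_site == 0L & outlier_site == 0L)
  if (n_floor > length(free)) abort("maf_floor_fraction too large for free sites")
  floor_site <- rep(FALSE, L)
  floor_site[sample(free, n_floor)] <- TRUE

  # subpopulation frequencies
  lo <- cfg$freq_range[1]
  hi <- cfg$freq_range[2]
  p0 <- truncate_unit(rbeta(L, cfg$freq_shape, cfg$freq_shape), lo, hi)
  c_bn <- cfg$base_fst
  bn <- function(p) {
    truncate_unit(rbeta(L, p * (1 - c_bn) / c_bn, (1 - p) * (1 - c_bn) / c_bn),
                  lo, hi)
  }
  p_lr <- bn(p0)
  p_ppb <- bn(p0)
  if (!is.null(regions) && nrow(regions) > 0) {
    in_region <- region_site > 0L
    mult <- regions$multiplier[region_site[in_region]]
    h_ppb <- runif(sum(in_region), cfg$region_het[1], cfg$region_het[2])
    h_lr <- mult * h_ppb
    if (any(h_lr > 0.5)) {
      bad <- regions[unique(region_site[in_region][h_lr > 0.5]), ]
      abort(paste0("infeasible multiplier in region ", bad$chrom[1], ":",
                   bad$start[1], "-", bad$end[1],
                   " (required heterozygosity > 0.5)"))
    }
    side <- sample(c(TRUE, FALSE), sum(in_region), replace = TRUE)
    p_ppb[in_region] <- freq_from_het(h_ppb, side)
    p_lr[in_region] <- freq_from_het(h_lr, side)
  }
  if (!is.null(outliers) && nrow(outliers) > 0) {
    io <- outlier_site > 0L
    dlt <- outliers$delta[outlier_site[io]]
    p_lr[io] <- (1 + dlt) / 2
    p_ppb[io] <- (1 - dlt) / 2
  }
  p_adm <- cfg$admixture * p_lr + (1 - cfg$admixture) * p_ppb

  ids <- c(
    sprintf("LR%03d", seq_len(cfg$n_landrace)),
    sprintf("PPB%03d", seq_len(cfg$n_ppb)),
    if (cfg$n_admixed > 0) sprintf("ADM%03d", seq_len(cfg$n_admixed))
  )
  groups <- c(rep("LANDRACE", cfg$n_landrace), rep("PPB", cfg$n_ppb),
              rep("ADMIXED", cfg$n_admixed))
  N <- length(ids)

  draw_rows <- function(p, n) {
    # n individuals x L sites with inbreeding F
    inbred <- matrix(runif(n * L) < cfg$inbreeding, n, L)
    hom <- matrix(2L * (runif(n * L) < rep(p, each = n)), n, L)
    outb <- matrix(rbinom(n * L, 2L, rep(p, each = n)), n, L)
    ifelse(inbred, hom, outb)
  }
  dosage <- rbind(
    draw_rows(p_lr, cfg$n_landrace),
    draw_rows(p_ppb, cfg$n_ppb),
    if (cfg$n_admixed > 0) draw_rows(p_adm, cfg$n_admixed)
  )
  storage.mode(dosage) <- "integer"

  # floor sites: monomorphic or, when the panel is large enough that a
  # single alternate chromosome stays at or below MAF 0.01, one heterozygote
  if (any(floor_site)) {
    fi <- which(floor_site)
    dosage[, fi] <- 0L
    if (1 / (2 * N) <= 0.01) {
      one_het <- fi[runif(length(fi)) < 0.5]
      carrier <- sample.int(N, length(one_het), replace = TRUE)
      dosage[cbind(carrier, one_het)] <- 1L
    }
  }

  # missingness, then re-draw any non-floor site whose realised MAF dips
  # to or below the filter cutoff
  mask <- matrix(runif(N * L) < cfg$missing_rate, N, L)
  dosage[mask] <- NA_integer_
  p_mat <- rbind(
    matrix(rep(p_lr, each = cfg$n_landrace), cfg$n_landrace, L),
    matrix(rep(p_ppb, each = cfg$n_ppb), cfg$n_ppb, L),
    if (cfg$n_admixed > 0) matrix(rep(p_adm, each = cfg$n_admixed), cfg$n_admixed, L)
  )
  for (iter in 1:20) {
    called <- colSums(!is.na(dosage))
    maf <- realized_maf(dosage)
    bad <- which(!floor_site & (maf <= 0.01 | (N - called) / N > 0.2))
    if (!length(bad)) break
    for (j in bad) {
      col <- draw_column(p_mat[, j], cfg$inbreeding)
      col[runif(N) < cfg$missing_rate] <- NA_integer_
      dosage[, j] <- col
    }
  }

  g <- genotype_matrix(dosage, dplyr::mutate(sites, ref = "A", alt = "G"), ids)
  map <- tibble(sample_id = ids, group = groups, is_reference = FALSE)
  truth <- list(
    p_landrace = p_lr, p_ppb = p_ppb, p_admixed = p_adm,
    sites = sites,
    region_site = region_site, outlier_site = outlier_site,
    floor_site = floor_site,
    planted_regions = regions, planted_outliers = outliers,
    seed = cfg$seed
  )
  list(genotypes = g, map = map, truth = truth)
}

truncate_unit <- function(p, lo, hi) pmin(pmax(p, lo), hi)

# p solving 2p(1-p) = h on the side requested (lower p if side is TRUE)
freq_from_het <- function(h, side) {
  root <- (1 - sqrt(pmax(0, 1 - 2 * h))) / 2
  ifelse(side, root, 1 - root)
}

draw_column <- function(p, f) {
  n <- length(p)
  inbred <- runif(n) < f
  as.integer(ifelse(inbred, 2L * (runif(n) < p), rbinom(n, 2L, p)))
}

realized_maf <- function(dosage) {
  called <- colSums(!is.na(dosage))
  freq <- ifelse(called > 0, colSums(dosage, na.rm = TRUE) / (2 * called), NA)
  pmin(freq, 1 - freq)
}

#' Simulate a neutral-equilibrium panel
#'
#' Draws each segregating site's alternate-allele count from the neutral
#' site-frequency spectrum (probability proportional to `1/i` copies) over
#' `2 * n_samples` chromosomes and assigns alleles to chromosomes at random
#' (outbred diploids). Under this law the pairwise-diversity and
#' segregating-sites estimators of theta have equal expectation, so
#' genome-mean Tajima's D is zero up to Monte-Carlo error -- the null the D
#' scan is validated against.
#'
#' @param n_samples Number of diploid samples.
#' @param n_sites Number of segregating sites.
#' @param n_chrom Number of chromosomes to spread sites over (default 5).
#' @param chrom_length Chromosome length in bp (default 2e7).
#' @param seed Integer seed.
#' @return A [genotype_matrix()].
#' @export
simulate_neutral_panel <- function(n_samples = 20, n_sites = 2000,
                                   n_chrom = 5, chrom_length = 2e7,
                                   seed = 1) {
  set.seed(seed)
  nc <- 2L * n_samples
  i <- seq_len(nc - 1)
  counts <- sample(i, n_sites, replace = TRUE, prob = 1 / i)
  dosage <- matrix(0L, n_samples, n_sites)
  for (j in seq_len(n_sites)) {
    alleles <- sample.int(nc, counts[j])
    ind <- (alleles - 1L) %/% 2L + 1L
    tab <- tabulate(ind, nbins = n_samples)
    dosage[, j] <- as.integer(tab)
  }
  chrom <- sim_chrom_name(rep(seq_len(n_chrom), length.out = n_sites))
  pos <- unlist(lapply(split(seq_len(n_sites), chrom), function(ix) {
    sort(sample.int(chrom_length, length(ix)))
  }), use.names = FALSE)
  ord <- order(chrom)
  sites <- tibble(chrom = chrom[ord], pos = pos, ref = "A", alt = "G")
  genotype_matrix(dosage[, ord, drop = FALSE], sites,
                  sprintf("N%03d", seq_len(n_samples)))
}

#' Simulate per-plot isotope phenotypes with known truth
#'
#' Forward model of the natural-abundance design: every environment carries
#' reference-line plots (`delta15N = ref + noise`) and, for each fixing
#' genotype, plots with
#' `delta15N = ref - (ndfa/100) * (ref - B) + noise`, so that the
#' %Ndfa estimator inverts the truth exactly at zero noise. Seed delta13C is
#' generated by inverting the discrimination formula from a drawn true
#' discrimination value, plus measurement noise. Genotype-level true %Ndfa
#' is drawn per breeding-history group.
#'
#' @param map Population map tibble (`sample_id`, `group`); fixing genotypes
#'   are its rows.
#' @param b_true True B value, per mil (default -2).
#' @param delta15n_ref True reference-line delta15N, per mil (default 3).
#' @param ndfa_mean Named vector of group mean %Ndfa (defaults follow the
#'   landrace/PPB contrast the trials report: landrace 46.4, PPB 40.1).
#' @param ndfa_sd Genotype-level %Ndfa standard deviation (default 6).
#' @param noise_sd Per-plot delta15N and delta13C measurement noise, per mil
#'   (default 0.2).
#' @param dc13_mean,dc13_sd Law of the true per-genotype discrimination
#'   (per mil; defaults 18.5 and 1).
#' @param n_plots Plots per fixing genotype (default 3 replicates).
#' @param n_ref_plots Reference-line plots per environment (default 6).
#' @param environment Environment label (default "YORITO").
#' @param reference_id Reference line id (default "R99").
#' @param seed Integer seed.
#' @return A list: `records` (per-plot isotope tibble as in
#'   [read_isotope_table()]) and `truth` (per-genotype true %Ndfa and
#'   discrimination, plus the generating constants).
#' @export
simulate_isotopes <- function(map,
                              b_true = -2, delta15n_ref = 3,
                              ndfa_mean = c(LANDRACE = 46.4, PPB = 40.1,
                                            CONVENTIONAL = 40.1, CHECK = 49.5,
                                            ADMIXED = 43.0),
                              ndfa_sd = 6, noise_sd = 0.2,
                              dc13_mean = 18.5, dc13_sd = 1,
                              n_plots = 3, n_ref_plots = 6,
                              environment = "YORITO",
                              reference_id = "R99", seed = 1) {
  set.seed(seed)
  if (delta15n_ref - b_true <= 0) {
    abort("simulate_isotopes: delta15n_ref must exceed b_true")
  }
  keep <- map$sample_id != reference_id
  if ("is_reference" %in% names(map)) keep <- keep & !(map$is_reference %in% TRUE)
  fixing <- map[keep, , drop = FALSE]
  mu <- ndfa_mean[fixing$group]
  if (any(is.na(mu))) {
    abort(paste0("simulate_isotopes: no ndfa_mean for group(s): ",
                 paste(unique(fixing$group[is.na(mu)]), collapse = ", ")))
  }
  true_ndfa <- truncate_unit(rnorm(nrow(fixing), mu, ndfa_sd), 2, 98)
  true_dc13 <- rnorm(nrow(fixing), dc13_mean, dc13_sd)
  geno <- tibble(
    genotype_id = fixing$sample_id, group = fixing$group,
    true_ndfa = true_ndfa, true_dc13 = true_dc13
  )
  fix_rows <- tidyr::crossing(geno, plot = seq_len(n_plots))
  fix_rows$delta15N <- delta15n_ref -
    (fix_rows$true_ndfa / 100) * (delta15n_ref - b_true) +
    rnorm(nrow(fix_rows), 0, noise_sd)
  fix_rows$delta13C <- delta13c_from_discrimination(fix_rows$true_dc13) +
    rnorm(nrow(fix_rows), 0, noise_sd)
  fix_rows$is_reference <- FALSE
  ref_rows <- tibble(
    genotype_id = reference_id, group = "CHECK",
    true_ndfa = NA_real_, true_dc13 = dc13_mean,
    plot = seq_len(n_ref_plots),
    delta15N = delta15n_ref + rnorm(n_ref_plots, 0, noise_sd),
    delta13C = delta13c_from_discrimination(dc13_mean) +
      rnorm(n_ref_plots, 0, noise_sd),
    is_reference = TRUE
  )
  records <- dplyr::bind_rows(fix_rows, ref_rows)
  records$environment <- environment
  records <- records[, c("genotype_id", "group", "environment", "plot",
                         "delta15N", "delta13C", "is_reference")]
  truth <- list(
    genotypes = geno, b_true = b_true, delta15n_ref_true = delta15n_ref,
    noise_sd = noise_sd, seed = seed
  )
  list(records = records, truth = truth)
}

#' Write the small deterministic fixtures used by the unit tests
#'
#' Emits, byte-identically on rerun: a 4-site toy VCF (plus a variant with a
#' triallelic record), a 3-sample population map listing the reference line,
#' a worked-example isotope table (including the delta13C = -28.2 row), and
#' a 4-taxon additive distance matrix.
#'
#' @param out_dir Output directory (created if needed).
#' @return Tibble of written file paths, invisibly.
#' @export
make_fixture_suite <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=Pv01>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3", "s4"), collapse = "\t"),
    "Pv01\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t0/0",
    "Pv01\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0/1\t0/1\t0/0\t1/1",
    "Pv01\t300\t.\tG\tA\t.\tPASS\t.\tGT\t./.\t0/0\t0/1\t0/0",
    "Pv01\t400\t.\tT\tC\t.\tPASS\t.\tGT\t1/1\t1/1\t0/1\t0/0"
  ), p("toy.vcf"))

  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=Pv01>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3", "s4"), collapse = "\t"),
    "Pv01\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t0/0",
    "Pv01\t150\t.\tC\tT,G\t.\tPASS\t.\tGT\t0/0\t1/2\t0/0\t0/0",
    "Pv01\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0/1\t0/1\t0/0\t1/1",
    "Pv01\t300\t.\tG\tA\t.\tPASS\t.\tGT\t./.\t0/0\t0/1\t0/0",
    "Pv01\t400\t.\tT\tC\t.\tPASS\t.\tGT\t1/1\t1/1\t0/1\t0/0"
  ), p("toy_triallelic.vcf"))

  writeLines(c(
    "sample_id\tgroup\tis_reference",
    "s1\tLANDRACE\tFALSE",
    "s2\tLANDRACE\tFALSE",
    "s3\tPPB\tFALSE",
    "R99\tCHECK\tTRUE"
  ), p("population_map.tsv"))

  writeLines(c(
    paste(c("genotype_id", "group", "environment", "plot", "delta15N",
            "delta13C", "is_reference"), collapse = "\t"),
    "R99\tCHECK\tYORITO\t1\t3.0\t-26.0\tTRUE",
    "R99\tCHECK\tYORITO\t2\t3.0\t-26.0\tTRUE",
    "HON34\tLANDRACE\tYORITO\t1\t1.5\t-28.2\tFALSE",
    "HON23\tPPB\tYORITO\t1\t2.0\t-24.5\tFALSE"
  ), p("isotopes.tsv"))

  # additive distances from the tree ((A:1,B:2):1.5,(C:1,D:3))
  writeLines(c(
    "\tA\tB\tC\tD",
    "A\t0\t3\t3.5\t5.5",
    "B\t3\t0\t4.5\t6.5",
    "C\t3.5\t4.5\t0\t4",
    "D\t5.5\t6.5\t4\t0"
  ), p("additive_distances.tsv"))

  invisible(tibble(path = c(p("toy.vcf"), p("toy_triallelic.vcf"),
                            p("population_map.tsv"), p("isotopes.tsv"),
                            p("additive_distances.tsv"))))
}
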