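#' Per-site nucleotide diversity
#'
#' The proportion of chromosome pairs that differ at a biallelic site:
#' \deqn{\pi_{site} = 2\,x\,(n-x) / (n(n-1))}
#' where `x` is the alternate-allele count among `n` sampled chromosomes.
#' This is the unbiased per-site estimator summed over sites by the windowed
#' scans.
#'
#' @param alt_count Alternate-allele count(s), `0 <= alt_count <= n_chrom`.
#' @param n_chrom Number of sampled chromosomes (>= 2). Recycled against
#'   `alt_count`.
#' @return Numeric vector of per-site diversity values in `[0, 1]`.
#' @export
#' @examples
#' site_pi(2, 4) # 4 of the 6 chromosome pairs differ
site_pi <- function(alt_count, n_chrom) {
  if (any(n_chrom < 2)) abort("site_pi: n_chrom must be >= 2")
  if (any(alt_count < 0 | alt_count > n_chrom)) {
    abort("site_pi: need 0 <= alt_count <= n_chrom")
  }
  2 * alt_count * (n_chrom - alt_count) / (n_chrom * (n_chrom - 1))
}

#' Constants for Tajima's D
#'
#' The sample-size-dependent constants of the standard D statistic
#' (harmonic sums a1, a2 and the derived b, c, e terms) for `n_chrom`
#' sampled chromosomes.
#'
#' @param n_chrom Number of sampled chromosomes (>= 2).
#' @return A one-row tibble with columns `n`, `a1`, `a2`, `b1`, `b2`,
#'   `c1`, `c2`, `e1`, `e2`.
#' @export
tajima_constants <- function(n_chrom) {
  n <- as.integer(n_chrom)
  if (is.na(n) || n < 2) abort("tajima_constants: n_chrom must be >= 2")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  tibble(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2,
         c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

# Shared per-site summaries for a sample subset: alt counts and callable
# chromosome counts, plus window assignment for a given grid.
site_stats <- function(g, samples = NULL) {
  if (!is.null(samples)) g <- subset_samples(g, samples)
  d <- g$dosage
  n_chrom <- 2L * colSums(!is.na(d))
  alt <- colSums(d, na.rm = TRUE)
  usable <- n_chrom >= 2L
  if (any(!usable)) {
    inform(sprintf("skipping %d site(s) with < 1 non-missing call", sum(!usable)))
  }
  tibble(
    chrom = g$sites$chrom, pos = g$sites$pos,
    n_chrom = as.integer(n_chrom), alt = as.integer(alt)
  )[usable, , drop = FALSE]
}

# Assign sites to windows over a tiled/sliding grid. Windows are 0-based
# half-open [start, end), containing 1-based pos iff start < pos <= end;
# chromosome length is the max observed position rounded up to a whole
# window. Only windows containing at least one site are materialised (the
# grid itself can be huge for 100 bp windows). Returns a window tibble plus
# a list-column-free parallel list of contained site indices.
assign_windows <- function(chrom, pos, size, step) {
  stopifnot(size > 0, step > 0, step <= size)
  n_back <- ceiling(size / step) # windows whose span can reach a given site
  per_chrom <- split(seq_along(pos), chrom)
  wins <- list()
  hits <- list()
  for (ch in names(per_chrom)) {
    ix <- per_chrom[[ch]]
    len <- ceiling(max(pos[ix]) / size) * size
    # candidate start indices k (start = k*step) per site: the last window
    # starting at or before pos-1, and up to n_back-1 windows before it
    k_last <- (pos[ix] - 1) %/% step
    cand <- unique(unlist(lapply(seq_len(n_back) - 1L, function(b) k_last - b)))
    cand <- sort(cand[cand >= 0 & cand * step < len])
    starts <- cand * step
    ends <- pmin(starts + size, len)
    contained <- lapply(seq_along(starts), function(i) {
      ix[pos[ix] > starts[i] & pos[ix] <= ends[i]]
    })
    keep <- lengths(contained) > 0
    wins[[ch]] <- tibble(chrom = ch, start = starts[keep], end = ends[keep])
    hits[[ch]] <- contained[keep]
  }
  list(windows = dplyr::bind_rows(wins), sites = do.call(c, unname(hits)))
}

#' Windowed nucleotide diversity
#'
#' Computes per-bp nucleotide diversity in windows across the genome: the sum
#' of [site_pi()] over contained SNPs divided by the full window size in bp
#' (monomorphic positions contribute zero implicitly, which is what puts
#' array-panel values at the 1e-7 to 1e-6 per-bp scale). Per-site chromosome
#' counts exclude missing calls. Windows containing no SNPs are omitted.
#'
#' @param g A [genotype_matrix()].
#' @param samples Optional character vector restricting the computation to a
#'   sample subset (e.g. one breeding-history group).
#' @param size Window size in bp (default 1 Mb).
#' @param step Window step in bp; defaults to `size` (non-overlapping tiles).
#' @return A tibble with one row per non-empty window: `chrom`, `start`,
#'   `end` (0-based half-open), `n_snps` and `pi`.
#' @export
windowed_pi <- function(g, samples = NULL, size = 1e6, step = size) {
  ss <- site_stats(g, samples)
  if (nrow(ss) == 0) abort("windowed_pi: no usable sites")
  aw <- assign_windows(ss$chrom, ss$pos, size, step)
  wins <- aw$windows
  pivals <- site_pi(ss$alt, ss$n_chrom)
  wins$n_snps <- lengths(aw$sites)
  wins$pi <- purrr::map_dbl(aw$sites, function(ix) sum(pivals[ix])) / size
  wins
}

#' Windowed Tajima's D
#'
#' Per window: `S` is the count of polymorphic sites, `k_hat` the mean
#' pairwise difference (the sum of [site_pi()] over contained sites, in site
#' units, not per-bp), and
#' \deqn{D = (\hat{k} - S/a_1) / \sqrt{e_1 S + e_2 S (S-1)}.}
#' `D` is `NA` when `S = 0`. The chromosome sample size used for the
#' constants is the modal non-missing chromosome count across the window's
#' sites (after [impute_missing()] this is simply twice the sample count).
#'
#' @inheritParams windowed_pi
#' @return A tibble with one row per non-empty window: `chrom`, `start`,
#'   `end`, `n_snps`, `S`, `k_hat`, `n_chrom` and `tajima_d`.
#' @export
windowed_tajima_d <- function(g, samples = NULL, size = 1e6, step = size) {
  ss <- site_stats(g, samples)
  if (nrow(ss) == 0) abort("windowed_tajima_d: no usable sites")
  aw <- assign_windows(ss$chrom, ss$pos, size, step)
  wins <- aw$windows
  hits <- aw$sites
  pivals <- site_pi(ss$alt, ss$n_chrom)
  seg <- ss$alt > 0L & ss$alt < ss$n_chrom
  wins$n_snps <- lengths(hits)
  const_cache <- new.env(parent = emptyenv())
  res <- purrr::map(hits, function(ix) {
    S <- sum(seg[ix])
    k_hat <- sum(pivals[ix])
    nc <- stat_mode(ss$n_chrom[ix])
    d <- NA_real_
    if (S > 0 && nc >= 2) {
      key <- as.character(nc)
      cons <- const_cache[[key]]
      if (is.null(cons)) {
        cons <- tajima_constants(nc)
        const_cache[[key]] <- cons
      }
      v <- cons$e1 * S + cons$e2 * S * (S - 1)
      d <- (k_hat - S / cons$a1) / sqrt(v)
    }
    c(S = S, k_hat = k_hat, n_chrom = nc, tajima_d = d)
  })
  res <- do.call(rbind, res)
  wins$S <- as.integer(unname(res[, "S"]))
  wins$k_hat <- unname(res[, "k_hat"])
  wins$n_chrom <- as.integer(unname(res[, "n_chrom"]))
  wins$tajima_d <- unname(res[, "tajima_d"])
  wins
}

# Modal value; ties broken toward the larger value (for chromosome counts the
# mode after imputation is unique anyway).
stat_mode <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}

#' Impute missing dosages by the site mode
#'
#' Deterministic single-pass imputation: every missing call is replaced by
#' the site's modal non-missing dosage, with ties broken toward the lower
#' dosage. Sites where all calls are missing are dropped. This stands in for
#' external statistical imputation and is adequate at the <3% missingness
#' typical of array panels.
#'
#' @param g A [genotype_matrix()].
#' @return A `genotype_matrix` with no missing calls; the fraction imputed is
#'   reported with a message.
#' @export
impute_missing <- function(g) {
  d <- g$dosage
  all_missing <- colSums(!is.na(d)) == 0
  if (any(all_missing)) {
    inform(sprintf("impute_missing: dropped %d all-missing site(s)", sum(all_missing)))
    d <- d[, !all_missing, drop = FALSE]
    g <- genotype_matrix(d, g$sites[!all_missing, , drop = FALSE], g$sample_ids)
    d <- g$dosage
  }
  n_missing <- sum(is.na(d))
  if (n_missing == 0) return(g)
  modes <- apply(d, 2, function(col) {
    tab <- tabulate(col + 1L, nbins = 3L)
    which.max(tab) - 1L # which.max takes the first maximum: lower dosage wins ties
  })
  miss <- which(is.na(d), arr.ind = TRUE)
  d[miss] <- modes[miss[, "col"]]
  inform(sprintf("impute_missing: imputed %.3f%% of calls",
                 100 * n_missing / length(d)))
  genotype_matrix(d, g$sites, g$sample_ids)
}
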