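#' Weir-Cockerham variance components for one site, two populations
#'
#' The 1984 moment estimator for r = 2 populations of diploids: among-
#' population (`a`), among-individual-within-population (`b`) and within-
#' individual (`c`) variance components, from per-population sample sizes,
#' alternate-allele frequencies and observed heterozygote frequencies. The
#' per-site estimate is `a / (a + b + c)`; windowed "weighted" F_ST sums the
#' components before taking the ratio.
#'
#' @param n1,n2 Numbers of non-missing diploid individuals (>= 2 each).
#' @param p1,p2 Alternate-allele sample frequencies.
#' @param h1,h2 Observed heterozygote frequencies (fraction of individuals
#'   that are heterozygous).
#'
#' All arguments are vectorised over sites.
#'
#' @return A tibble with columns `a`, `b`, `c`.
#' @export
#' @examples
#' # a fixed difference gives a/(a+b+c) = 1
#' w <- fst_site_components(n1 = 10, p1 = 1, h1 = 0, n2 = 10, p2 = 0, h2 = 0)
#' with(w, a / (a + b + c))
fst_site_components <- function(n1, p1, h1, n2, p2, h2) {
  if (any(n1 < 2 | n2 < 2)) {
    abort("fst_site_components: both populations need >= 2 individuals")
  }
  r <- 2
  n_bar <- (n1 + n2) / 2
  n_c <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  tibble(a = a, b = b, c = cc)
}

#' Windowed Weir-Cockerham F_ST between two groups
#'
#' Computes per-site variance components between two population-map groups
#' and aggregates them in windows: `fst_weighted` is the ratio-of-sums
#' \eqn{\sum a / \sum (a+b+c)} over the window's sites and `fst_mean` the
#' mean of per-site ratios. With the default 100 bp windows on array data
#' most windows contain a single SNP, so windowed and per-site values
#' coincide; `pos` carries the SNP position for single-SNP windows (the
#' window midpoint otherwise). Sites where either group has fewer than two
#' non-missing individuals are skipped with a message; windows without
#' usable sites, or with a non-positive component sum, are omitted.
#' Negative estimates are reported as computed, not clamped.
#'
#' @param g A [genotype_matrix()].
#' @param map Population map tibble (see [read_population_map()]).
#' @param group_a,group_b Group labels to contrast; each must map to at least
#'   two samples present in `g`.
#' @param size Window size in bp (default 100).
#' @param step Window step in bp; defaults to `size`.
#' @return A tibble with one row per emitted window: `chrom`, `start`, `end`,
#'   `pos`, `n_snps`, `sum_a`, `sum_abc`, `fst_weighted`, `fst_mean`.
#' @export
windowed_fst <- function(g, map, group_a, group_b, size = 100, step = size) {
  sa <- intersect(map$sample_id[map$group == group_a], g$sample_ids)
  sb <- intersect(map$sample_id[map$group == group_b], g$sample_ids)
  if (length(sa) < 2 || length(sb) < 2) {
    abort("windowed_fst: both groups need >= 2 genotyped samples")
  }
  comp <- fst_components_by_site(g, sa, sb)
  if (nrow(comp) == 0) abort("windowed_fst: no site usable in both groups")
  aw <- assign_windows(comp$chrom, comp$pos, size, step)
  wins <- aw$windows
  hits <- aw$sites
  wins$n_snps <- lengths(hits)
  agg <- purrr::map(hits, function(ix) {
    sum_a <- sum(comp$a[ix])
    sum_abc <- sum(comp$a[ix] + comp$b[ix] + comp$c[ix])
    ratio <- with(comp[ix, ], a / (a + b + c))
    c(
      sum_a = sum_a, sum_abc = sum_abc,
      fst_weighted = if (sum_abc > 0) sum_a / sum_abc else NA_real_,
      fst_mean = mean(ratio[is.finite(ratio)]),
      pos = if (length(ix) == 1) comp$pos[ix] else NA_real_
    )
  })
  agg <- do.call(rbind, agg)
  wins$pos <- ifelse(is.na(agg[, "pos"]),
                     as.integer((wins$start + wins$end) / 2), agg[, "pos"])
  wins$pos <- as.integer(wins$pos)
  wins$sum_a <- agg[, "sum_a"]
  wins$sum_abc <- agg[, "sum_abc"]
  wins$fst_weighted <- agg[, "fst_weighted"]
  wins$fst_mean <- agg[, "fst_mean"]
  wins <- wins[!is.na(wins$fst_weighted), , drop = FALSE]
  wins[, c("chrom", "start", "end", "pos", "n_snps",
           "sum_a", "sum_abc", "fst_weighted", "fst_mean")]
}

# Per-site components for two fixed sample sets; drops sites with < 2
# non-missing individuals in either group.
fst_components_by_site <- function(g, samples_a, samples_b) {
  da <- g$dosage[samples_a, , drop = FALSE]
  db <- g$dosage[samples_b, , drop = FALSE]
  n1 <- colSums(!is.na(da))
  n2 <- colSums(!is.na(db))
  ok <- n1 >= 2 & n2 >= 2
  if (any(!ok)) {
    inform(sprintf("windowed_fst: skipped %d site(s) with < 2 calls in a group",
                   sum(!ok)))
  }
  if (!any(ok)) {
    return(tibble(chrom = character(), pos = integer(),
                  a = double(), b = double(), c = double()))
  }
  da <- da[, ok, drop = FALSE]
  db <- db[, ok, drop = FALSE]
  n1 <- n1[ok]
  n2 <- n2[ok]
  p1 <- colSums(da, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(db, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(da == 1L, na.rm = TRUE) / n1
  h2 <- colSums(db == 1L, na.rm = TRUE) / n2
  comp <- fst_site_components(n1, p1, h1, n2, p2, h2)
  dplyr::bind_cols(
    tibble(chrom = g$sites$chrom[ok], pos = g$sites$pos[ok]),
    comp
  )
}
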