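#' Genotype matrix for a biallelic SNP panel
#'
#' Container for a samples x sites panel of biallelic SNP dosages, the unit
#' every population-genetic computation in the package operates on. Dosage is
#' the per-sample count of alternate alleles (0, 1 or 2 for a diploid; `NA`
#' for a missing call). Sites are kept sorted by chromosome then position.
#'
#' @param dosage Integer matrix, samples in rows, sites in columns. Values
#'   must be 0, 1, 2 or `NA`. Row names, if present, are taken as sample ids.
#' @param sites Data frame with one row per site and columns `chrom`
#'   (character), `pos` (1-based bp), `ref` and `alt` (single-base alleles).
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to the row names of `dosage`.
#'
#' @return An object of class `genotype_matrix` with elements `dosage`
#'   (matrix), `sites` (tibble) and `sample_ids` (character). Ploidy is
#'   fixed at 2.
#' @export
#' @examples
#' g <- genotype_matrix(
#'   dosage = rbind(s1 = c(0L, 2L), s2 = c(1L, 2L)),
#'   sites = data.frame(chrom = "Pv01", pos = c(100, 200), ref = "A", alt = "G")
#' )
#' n_sites(g)
genotype_matrix <- function(dosage, sites, sample_ids = rownames(dosage)) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  sites <- as_tibble(sites)
  if (is.null(sample_ids)) {
    sample_ids <- paste0("sample", seq_len(nrow(dosage)))
  }
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) {
    abort("sample ids must be unique")
  }
  if (length(sample_ids) != nrow(dosage)) {
    abort("length of `sample_ids` must match rows of `dosage`")
  }
  required <- c("chrom", "pos", "ref", "alt")
  if (!all(required %in% names(sites))) {
    abort(paste0("`sites` needs columns: ", paste(required, collapse = ", ")))
  }
  if (nrow(sites) != ncol(dosage)) {
    abort("rows of `sites` must match columns of `dosage`")
  }
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) {
    abort("dosage values must be 0, 1, 2 or NA")
  }
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  dosage <- dosage[, ord, drop = FALSE]
  if (anyDuplicated(sites[, c("chrom", "pos")])) {
    abort("site positions must be strictly increasing within a chromosome")
  }
  rownames(dosage) <- sample_ids
  colnames(dosage) <- paste0(sites$chrom, ":", sites$pos)
  structure(
    list(dosage = dosage, sites = sites, sample_ids = sample_ids, ploidy = 2L),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d samples x %d biallelic sites on %d chromosome(s)\n",
    length(x$sample_ids), nrow(x$sites), length(unique(x$sites$chrom))
  ))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param g A `genotype_matrix`.
#' @export
n_sites <- function(g) nrow(g$sites)

#' @rdname genotype_matrix
#' @export
n_samples <- function(g) length(g$sample_ids)

#' Subset a genotype matrix by sample
#'
#' @param g A [genotype_matrix()].
#' @param samples Character vector of sample ids to keep (order preserved).
#' @return A `genotype_matrix` restricted to `samples`; all sites are kept.
#' @export
subset_samples <- function(g, samples) {
  samples <- as.character(samples)
  missing <- setdiff(samples, g$sample_ids)
  if (length(missing)) {
    abort(paste0("samples not in panel: ", paste(missing, collapse = ", ")))
  }
  if (!length(samples)) abort("`samples` must be non-empty")
  genotype_matrix(g$dosage[samples, , drop = FALSE], g$sites, samples)
}

#' Per-site allele summaries
#'
#' Alternate-allele counts and frequencies computed on non-missing calls only,
#' the convention used throughout for array data QC.
#'
#' @param g A [genotype_matrix()].
#' @return A tibble with one row per site: `chrom`, `pos`, `n_chrom`
#'   (non-missing chromosomes), `alt_count`, `alt_freq`, `maf` and
#'   `missingness` (fraction of samples with a missing call).
#' @export
allele_summary <- function(g) {
  d <- g$dosage
  n_called <- colSums(!is.na(d))
  alt <- colSums(d, na.rm = TRUE)
  n_chrom <- 2L * n_called
  freq <- ifelse(n_chrom > 0, alt / n_chrom, NA_real_)
  tibble(
    chrom = g$sites$chrom,
    pos = g$sites$pos,
    n_chrom = as.integer(n_chrom),
    alt_count = as.integer(alt),
    alt_freq = freq,
    maf = pmin(freq, 1 - freq),
    missingness = 1 - n_called / nrow(d)
  )
}
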