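#' Allele-sharing distance between samples
#'
#' Pairwise p-distance on dosages: the mean per-site allele difference
#' \eqn{|d_i - d_j| / 2} over sites where both samples are called. This is
#' the defensible distance for biallelic array dosages (substitution-model
#' distances are not identifiable from array data) and feeds the
#' neighbor-joining tree.
#'
#' @param g A [genotype_matrix()] with >= 2 samples.
#' @return A symmetric matrix (zero diagonal, values in `[0, 1]`) with
#'   sample ids as dimnames. A sample pair with no jointly called site is
#'   an error.
#' @export
pairwise_distance <- function(g) {
  if (n_samples(g) < 2) abort("pairwise_distance: need >= 2 samples")
  d <- g$dosage
  called <- (!is.na(d)) * 1
  joint <- tcrossprod(called) # jointly called site counts
  if (any(joint[upper.tri(joint)] == 0)) {
    abort("pairwise_distance: a sample pair shares no called site")
  }
  # |d_i - d_j| decomposes over dosage-class indicators: 1 for {0,1} or
  # {1,2} pairs, 2 for {0,2} pairs
  i0 <- (d == 0L & !is.na(d)) * 1
  i1 <- (d == 1L & !is.na(d)) * 1
  i2 <- (d == 2L & !is.na(d)) * 1
  mism <- tcrossprod(i0, i1) + tcrossprod(i1, i0) +
    tcrossprod(i1, i2) + tcrossprod(i2, i1) +
    2 * (tcrossprod(i0, i2) + tcrossprod(i2, i0))
  dist <- (mism / 2) / joint
  diag(dist) <- 0
  dimnames(dist) <- list(g$sample_ids, g$sample_ids)
  dist
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic agglomerative neighbor joining (via \pkg{ape}), followed by a
#' deterministic clean-up of negative branch lengths: a negative edge is set
#' to zero and its deficit transferred to the adjacent sibling edge so path
#' lengths through the pair are preserved (standard practice for distance
#' trees).
#'
#' @param d Symmetric distance matrix with >= 3 labelled samples.
#' @return An unrooted `phylo` tree with branch lengths in distance units.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) abort("neighbor_joining: need >= 3 samples")
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    abort("neighbor_joining: distance matrix must be symmetric")
  }
  tree <- ape::nj(stats::as.dist(d))
  clamp_negative_edges(tree)
}

# Zero out negative branch lengths, moving each deficit onto the sibling
# edge under the same parent (second pass clamps any residual negatives).
clamp_negative_edges <- function(tree) {
  el <- tree$edge.length
  for (i in which(el < 0)) {
    parent <- tree$edge[i, 1]
    sibs <- which(tree$edge[, 1] == parent & seq_along(el) != i)
    if (length(sibs)) {
      el[sibs[1]] <- el[sibs[1]] + el[i]
    }
    el[i] <- 0
  }
  el[el < 0] <- 0
  tree$edge.length <- el
  tree
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples site columns with replacement, rebuilds the distance tree per
#' replicate, and reports for each internal edge the fraction of replicates
#' containing the same bipartition. Reproducible under `seed`.
#'
#' @param g A [genotype_matrix()].
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for the resampling.
#' @return The [neighbor_joining()] tree of the full panel, with node labels
#'   set to support fractions in `[0, 1]` (also attached as the
#'   `support` attribute).
#' @export
bootstrap_support <- function(g, replicates = 1000, seed = 1) {
  if (replicates < 1) abort("bootstrap_support: replicates must be >= 1")
  build <- function(mat) {
    gg <- genotype_matrix(mat, tibble(
      chrom = "boot", pos = seq_len(ncol(mat)),
      ref = "A", alt = "G"
    ))
    neighbor_joining(pairwise_distance(gg))
  }
  tree <- neighbor_joining(pairwise_distance(g))
  set.seed(seed)
  counts <- ape::boot.phylo(tree, g$dosage, build, B = replicates,
                            quiet = TRUE, rooted = FALSE)
  support <- counts / replicates
  tree$node.label <- ifelse(is.na(support), "", format(support, trim = TRUE))
  attr(tree, "support") <- support
  tree
}

#' Principal component analysis of a genotype panel
#'
#' Centres each site by its mean dosage (missing calls mean-imputed for the
#' decomposition) and eigendecomposes the sample covariance. By default no
#' variance scaling is applied; `scale = TRUE` switches to a
#' frequency-scaled PCA for sensitivity checks.
#'
#' @param g A [genotype_matrix()] with >= 3 samples.
#' @param n_components Number of components to return (truncated to the rank
#'   with a message if too large).
#' @param scale Scale sites to unit variance as well (default `FALSE`).
#' @return An object of class `genotype_pca`: `scores` (tibble `sample_id` +
#'   `PC` columns), `var_explained` (fractions over all components,
#'   non-increasing, summing to 1) and `sdev`.
#' @export
genotype_pca <- function(g, n_components = 2, scale = FALSE) {
  if (n_samples(g) < 3) abort("genotype_pca: need >= 3 samples")
  m <- g$dosage
  mu <- colMeans(m, na.rm = TRUE)
  idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(idx)) m[idx] <- mu[idx[, "col"]]
  keep <- apply(m, 2, function(col) stats::var(col) > 0)
  m <- m[, keep, drop = FALSE]
  pc <- prcomp(m, center = TRUE, scale. = scale)
  pos <- pc$sdev^2 > 1e-12 * pc$sdev[1]^2
  rank <- sum(pos)
  if (n_components > rank) {
    inform(sprintf("genotype_pca: truncating to rank %d", rank))
    n_components <- rank
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(
      scores = dplyr::bind_cols(
        tibble(sample_id = g$sample_ids),
        as_tibble(pc$x[, seq_len(n_components), drop = FALSE])
      ),
      var_explained = ve,
      sdev = pc$sdev,
      n_components = n_components
    ),
    class = "genotype_pca"
  )
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat(sprintf("<genotype_pca> %d samples, %d component(s); PC1 %.1f%% of variance\n",
              nrow(x$scores), x$n_components, 100 * x$var_explained[1]))
  invisible(x)
}

#' @rdname genotype_pca
#' @param x A `genotype_pca`.
#' @param ... Unused.
#' @export
tidy.genotype_pca <- function(x, ...) {
  tidyr::pivot_longer(x$scores, -"sample_id",
                      names_to = "component", values_to = "score")
}

#' @rdname genotype_pca
#' @export
glance.genotype_pca <- function(x, ...) {
  tibble(
    n_samples = nrow(x$scores),
    n_components = x$n_components,
    pc1_var = x$var_explained[1],
    pc2_var = if (length(x$var_explained) > 1) x$var_explained[2] else NA_real_
  )
}

#' Write a tree (with supports) as newick
#'
#' @param tree A `phylo`, e.g. from [bootstrap_support()]; node labels carry
#'   support values.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
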