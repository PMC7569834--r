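#' Plot windowed diversity for two groups along the genome
#'
#' @param wins_a,wins_b Window tibbles from [windowed_pi()].
#' @param labels Length-2 character vector naming the groups.
#' @param regions Optional region tibble from [call_high_diversity_regions()]
#'   to shade.
#' @return A ggplot faceted by chromosome: per-bp diversity against window
#'   midpoint (Mbp).
#' @export
plot_diversity_scan <- function(wins_a, wins_b,
                                labels = c("landrace", "PPB"),
                                regions = NULL) {
  both <- dplyr::bind_rows(
    dplyr::mutate(wins_a, group = labels[1]),
    dplyr::mutate(wins_b, group = labels[2])
  )
  both$mid <- (both$start + both$end) / 2e6
  p <- ggplot2::ggplot(both, ggplot2::aes(.data$mid, .data$pi, colour = .data$group)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mbp)", y = "nucleotide diversity (per bp)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(regions) && nrow(regions) > 0) {
    regions <- dplyr::mutate(regions, xmin = .data$start / 1e6, xmax = .data$end / 1e6)
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "steelblue"
    )
  }
  p
}

#' Manhattan-style plot of windowed weighted F_ST
#'
#' @param fst Tibble from [windowed_fst()].
#' @param threshold Significance cutoff drawn as a horizontal line and used
#'   to highlight outlier windows (default 0.5).
#' @return A ggplot faceted by chromosome.
#' @export
plot_fst_scan <- function(fst, threshold = 0.5) {
  fst$outlier <- !is.na(fst$fst_weighted) & fst$fst_weighted > threshold
  ggplot2::ggplot(fst, ggplot2::aes(.data$pos / 1e6, .data$fst_weighted,
                                    colour = .data$outlier)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mbp)", y = expression(weighted ~ F[ST])) +
    ggplot2::theme_minimal()
}

#' @describeIn genotype_pca Scatter of the first two PCs, optionally coloured
#'   by population-map group.
#' @param object A `genotype_pca` (or `gt_biplot`).
#' @param map Optional population map tibble to colour samples by group.
#' @export
autoplot.genotype_pca <- function(object, map = NULL, ...) {
  scores <- object$scores
  if (!is.null(map)) {
    scores <- dplyr::left_join(scores, map[, c("sample_id", "group")],
                               by = "sample_id")
  } else {
    scores$group <- "panel"
  }
  ggplot2::ggplot(scores, ggplot2::aes(.data$PC1, .data$PC2, colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2]),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn gt_biplot Genotype-by-trait biplot: genotype scores as points,
#'   trait loadings as labelled vectors (acute angles mark positive trait
#'   correlations).
#' @param object A `gt_biplot`.
#' @export
autoplot.gt_biplot <- function(object, ...) {
  sc <- object$scores
  ld <- object$loadings
  r <- max(abs(c(sc$PC1, sc$PC2))) / max(abs(c(ld$PC1, ld$PC2)))
  ld <- dplyr::mutate(ld, PC1 = .data$PC1 * r, PC2 = .data$PC2 * r)
  ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_point(colour = "grey40", size = 1) +
    ggplot2::geom_segment(
      data = ld,
      ggplot2::aes(x = 0, y = 0, xend = .data$PC1, yend = .data$PC2),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "firebrick"
    ) +
    ggplot2::geom_text(data = ld, ggplot2::aes(label = .data$trait),
                       colour = "firebrick", vjust = -0.5, size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])
    ) +
    ggplot2::theme_minimal()
}
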