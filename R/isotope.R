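#' Configuration for isotope-derived traits
#'
#' @param b The B value in per mil: the average seed delta15N of beans grown
#'   with atmospheric fixation as their only nitrogen source. It is a
#'   required calibration constant of the natural-abundance method; see
#'   [estimate_b_value()] to derive it from N-free growth-room records.
#' @param delta13c_air Atmospheric delta13C in per mil (default -8, the
#'   approximate current free-atmosphere value).
#' @param normalize If `TRUE`, delta15N values are centred per environment
#'   before %Ndfa is computed (off by default; raw values are used).
#' @return A list of class `isotope_config`.
#' @export
isotope_config <- function(b, delta13c_air = -8, normalize = FALSE) {
  if (!is.numeric(b) || length(b) != 1 || is.na(b)) {
    abort("isotope_config: `b` must be a single number (per mil)")
  }
  structure(list(b = b, delta13c_air = delta13c_air, normalize = normalize),
            class = "isotope_config")
}

#' Estimate the B value from N-free reference records
#'
#' The B value is the arithmetic mean seed delta15N of genotypes grown where
#' the entire N source is atmospheric fixation (N-free media).
#'
#' @param delta15n Numeric vector of per-mil delta15N measurements (>= 1).
#' @return The mean, in per mil.
#' @export
estimate_b_value <- function(delta15n) {
  delta15n <- delta15n[!is.na(delta15n)]
  if (length(delta15n) == 0) abort("estimate_b_value: no records")
  mean(delta15n)
}

#' Percent nitrogen derived from the atmosphere
#'
#' The 15N natural-abundance estimator:
#' \deqn{\%Ndfa = 100\,(\delta^{15}N_{ref} - \delta^{15}N_{fix}) /
#'   (\delta^{15}N_{ref} - B)}
#' where the reference is a non-fixing line grown alongside the fixing
#' genotypes. Values are not clamped; estimates outside `[0, 100]` are the
#' caller's signal of noise or calibration problems (see the
#' `out_of_range` flag added by [ndfa_table()]).
#'
#' @param delta15n_ref Reference-plant delta15N, per mil.
#' @param delta15n_fix Fixing-plant delta15N, per mil.
#' @param b The B value, per mil; must differ from `delta15n_ref`.
#' @return %Ndfa values (vectorised).
#' @export
#' @examples
#' percent_ndfa(4, 1, -2) # 50%
percent_ndfa <- function(delta15n_ref, delta15n_fix, b) {
  denom <- delta15n_ref - b
  if (any(denom == 0, na.rm = TRUE)) {
    abort("percent_ndfa: delta15n_ref equals B; denominator undefined")
  }
  100 * (delta15n_ref - delta15n_fix) / denom
}

#' Carbon isotope discrimination
#'
#' Converts seed delta13C to discrimination
#' \deqn{\Delta^{13}C = (\delta_{air} - \delta_{plant}) / (1 + \delta_{plant})}
#' with the deltas in fractional units (per mil / 1000); the result is
#' returned in per mil. Discrimination decreases as plant delta13C rises,
#' and lower discrimination indicates higher water use efficiency.
#'
#' @param delta13c_plant Seed delta13C, per mil.
#' @param delta13c_air Atmospheric delta13C, per mil (default -8).
#' @return Discrimination in per mil (vectorised).
#' @export
#' @examples
#' carbon_discrimination(-28.2) # ~20.79 per mil
carbon_discrimination <- function(delta13c_plant, delta13c_air = -8) {
  dp <- delta13c_plant / 1000
  da <- delta13c_air / 1000
  1000 * (da - dp) / (1 + dp)
}

# Inverse of carbon_discrimination: the plant delta13C that yields a given
# discrimination. Used by the forward simulator.
delta13c_from_discrimination <- function(delta_cap, delta13c_air = -8) {
  Dc <- delta_cap / 1000
  da <- delta13c_air / 1000
  1000 * (da - Dc) / (1 + Dc)
}

#' Fill %Ndfa and discrimination into a per-plot isotope table
#'
#' For each environment, the reference delta15N is the mean over that
#' environment's reference-line plots; [percent_ndfa()] is then applied to
#' every non-reference record, and [carbon_discrimination()] to every
#' delta13C value. With `normalize = TRUE` in the config, delta15N values
#' are centred on the environment mean first (%Ndfa is unchanged by a
#' common shift, so this only matters for reporting).
#'
#' @param records Per-plot isotope tibble (see [read_isotope_table()]).
#' @param cfg An [isotope_config()].
#' @return `records` with added columns `delta15n_ref` (the environment's
#'   reference mean), `ndfa_percent` (`NA` for reference rows),
#'   `out_of_range` (flag for estimates outside `[0, 100]`) and
#'   `delta_cap_13c`.
#' @export
ndfa_table <- function(records, cfg) {
  if (!inherits(cfg, "isotope_config")) abort("`cfg` must be an isotope_config")
  records <- as_tibble(records)
  if (!"environment" %in% names(records)) records$environment <- "ENV1"
  if (cfg$normalize) {
    records <- dplyr::mutate(records,
      delta15N = .data$delta15N - mean(.data$delta15N, na.rm = TRUE),
      .by = "environment"
    )
  }
  refs <- dplyr::summarise(
    dplyr::filter(records, .data$is_reference),
    delta15n_ref = mean(.data$delta15N, na.rm = TRUE),
    .by = "environment"
  )
  missing_env <- setdiff(unique(records$environment), refs$environment)
  if (length(missing_env)) {
    abort(paste0("ndfa_table: no reference-line records in environment(s): ",
                 paste(missing_env, collapse = ", ")))
  }
  if (any(refs$delta15n_ref - cfg$b <= 0)) {
    abort("ndfa_table: reference delta15N must exceed B (denominator <= 0)")
  }
  out <- dplyr::left_join(records, refs, by = "environment")
  out$ndfa_percent <- ifelse(
    out$is_reference, NA_real_,
    percent_ndfa(out$delta15n_ref, out$delta15N, cfg$b)
  )
  out$out_of_range <- !is.na(out$ndfa_percent) &
    (out$ndfa_percent < 0 | out$ndfa_percent > 100)
  out$delta_cap_13c <- carbon_discrimination(out$delta13C, cfg$delta13c_air)
  out
}

#' Pairwise Pearson correlations for a genotype x trait table
#'
#' Pairwise-complete Pearson correlations between trait columns; cells with
#' fewer than `min_pairs` complete observation pairs are reported as `NA`.
#'
#' @param traits Data frame with one row per genotype: an id column (any
#'   non-numeric columns are ignored) and numeric trait columns.
#' @param min_pairs Minimum complete pairs required per cell (default 3).
#' @return A symmetric correlation matrix (unit diagonal) over the trait
#'   columns.
#' @export
pearson_matrix <- function(traits, min_pairs = 3) {
  num <- as.data.frame(traits)[vapply(traits, is.numeric, logical(1))]
  if (ncol(num) < 2) abort("pearson_matrix: need >= 2 numeric trait columns")
  m <- as.matrix(num)
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  ok <- crossprod(!is.na(m)) # complete pairs per cell
  r[ok < min_pairs] <- NA_real_
  diag(r) <- 1
  r
}

#' Genotype x trait biplot decomposition
#'
#' Standardises each trait (zero mean, unit variance), drops genotypes with
#' any missing cell (reported), and eigendecomposes the standardised table.
#' Loadings follow the correlation-biplot convention (eigenvectors scaled by
#' component standard deviations), so trait vectors at acute angles
#' correspond to positively correlated traits and obtuse angles to negative
#' correlations.
#'
#' @param traits Data frame with a `genotype_id` column (or the first
#'   non-numeric column is used as the id) and numeric trait columns. Needs
#'   at least 3 complete genotypes and 2 traits.
#' @param n_components Number of components to retain (default 2).
#' @return An object of class `gt_biplot` with elements `scores` (tibble:
#'   `genotype_id` + `PC` columns), `loadings` (tibble: `trait` + `PC`
#'   columns), `var_explained` (fractions, non-increasing) and `n_dropped`.
#' @export
gt_biplot <- function(traits, n_components = 2) {
  traits <- as_tibble(traits)
  is_num <- vapply(traits, is.numeric, logical(1))
  if (sum(is_num) < 2) abort("gt_biplot: need >= 2 numeric trait columns")
  id_col <- if ("genotype_id" %in% names(traits)) "genotype_id" else
    names(traits)[!is_num][1]
  ids <- if (is.na(id_col) || is.null(id_col)) {
    as.character(seq_len(nrow(traits)))
  } else {
    as.character(traits[[id_col]])
  }
  m <- as.matrix(traits[is_num])
  complete <- stats::complete.cases(m)
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    inform(sprintf("gt_biplot: dropped %d genotype(s) with missing cells", n_dropped))
  }
  m <- m[complete, , drop = FALSE]
  ids <- ids[complete]
  if (nrow(m) < 3) abort("gt_biplot: need >= 3 complete genotypes")
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  k <- min(n_components, ncol(pc$rotation))
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  # correlation-biplot convention: loadings are eigenvectors scaled by the
  # component standard deviations, so cosines between trait vectors
  # approximate trait correlations
  load_mat <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2,
                    pc$sdev[seq_len(k)], "*")
  structure(
    list(
      scores = dplyr::bind_cols(tibble(genotype_id = ids),
                                as_tibble(pc$x[, seq_len(k), drop = FALSE])),
      loadings = dplyr::bind_cols(tibble(trait = colnames(m)),
                                  as_tibble(load_mat)),
      var_explained = ve[seq_len(k)],
      sdev = pc$sdev,
      n_dropped = n_dropped
    ),
    class = "gt_biplot"
  )
}

#' @export
print.gt_biplot <- function(x, ...) {
  cat(sprintf("<gt_biplot> %d genotypes x %d traits; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), nrow(x$loadings),
              100 * x$var_explained[1],
              if (length(x$var_explained) > 1) 100 * x$var_explained[2] else NA))
  invisible(x)
}

#' @rdname gt_biplot
#' @param x A `gt_biplot`.
#' @param ... Unused.
#' @export
tidy.gt_biplot <- function(x, ...) {
  scores <- tidyr::pivot_longer(x$scores, -"genotype_id",
                                names_to = "component", values_to = "value")
  scores$term <- scores$genotype_id
  scores$kind <- "score"
  loads <- tidyr::pivot_longer(x$loadings, -"trait",
                               names_to = "component", values_to = "value")
  loads$term <- loads$trait
  loads$kind <- "loading"
  dplyr::bind_rows(scores[, c("kind", "term", "component", "value")],
                   loads[, c("kind", "term", "component", "value")])
}

#' @rdname gt_biplot
#' @export
glance.gt_biplot <- function(x, ...) {
  tibble(
    n_genotypes = nrow(x$scores),
    n_traits = nrow(x$loadings),
    n_dropped = x$n_dropped,
    pc1_var = x$var_explained[1],
    pc2_var = if (length(x$var_explained) > 1) x$var_explained[2] else NA_real_
  )
}
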