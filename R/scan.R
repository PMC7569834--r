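#' Call regions of elevated diversity in one group relative to another
#'
#' Implements the diversity-contrast region rule: a window qualifies when
#' group A's per-bp diversity exceeds `ratio_threshold` times group B's
#' (window-by-window, on identical window grids). Adjacent qualifying
#' windows on a chromosome (sharing a boundary) are merged, and merged
#' regions shorter than `min_length` bp are dropped. A window with
#' `pi_b = 0` qualifies iff `pi_a > 0`; its ratio is recorded as `Inf`.
#'
#' @param wins_a,wins_b Window tibbles from [windowed_pi()] for the two
#'   groups. Only windows defined (non-empty) in both groups are compared;
#'   the two inputs must come from the same window grid.
#' @param ratio_threshold Minimum A/B diversity ratio (default 3).
#' @param min_length Minimum merged-region length in bp (default 25,000).
#' @return A tibble of merged regions sorted by (chrom, start): `chrom`,
#'   `start`, `end`, `n_windows`, `pi_a`, `pi_b` (means over constituent
#'   windows) and `ratio`.
#' @export
call_high_diversity_regions <- function(wins_a, wins_b,
                                        ratio_threshold = 3,
                                        min_length = 25000) {
  shared <- dplyr::inner_join(
    dplyr::select(wins_a, "chrom", "start", "end", pi_a = "pi"),
    dplyr::select(wins_b, "chrom", "start", "end", pi_b = "pi"),
    by = c("chrom", "start", "end")
  )
  # grids must match: any A/B window pair that overlaps must be identical
  only_a <- dplyr::anti_join(wins_a, wins_b, by = c("chrom", "start", "end"))
  if (nrow(only_a) > 0 && nrow(wins_b) > 0) {
    for (i in seq_len(nrow(only_a))) {
      clash <- wins_b$chrom == only_a$chrom[i] &
        wins_b$start < only_a$end[i] & wins_b$end > only_a$start[i]
      if (any(clash)) {
        abort("call_high_diversity_regions: window grids do not match")
      }
    }
  }
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  n_windows = integer(), pi_a = double(), pi_b = double(),
                  ratio = double())
  if (nrow(shared) == 0) return(empty)
  qual <- shared$pi_a > ratio_threshold * shared$pi_b & shared$pi_a > 0
  shared <- shared[qual, , drop = FALSE]
  if (nrow(shared) == 0) return(empty)
  shared <- dplyr::arrange(shared, .data$chrom, .data$start)
  new_run <- c(TRUE, shared$chrom[-1] != shared$chrom[-nrow(shared)] |
                 shared$start[-1] != shared$end[-nrow(shared)])
  shared$run <- cumsum(new_run)
  out <- dplyr::summarise(
    dplyr::group_by(shared, .data$run),
    chrom = .data$chrom[1],
    start = min(.data$start),
    end = max(.data$end),
    n_windows = dplyr::n(),
    pi_a = mean(.data$pi_a),
    pi_b = mean(.data$pi_b),
    .groups = "drop"
  )
  out$ratio <- ifelse(out$pi_b > 0, out$pi_a / out$pi_b, Inf)
  out <- out[out$end - out$start >= min_length,
             c("chrom", "start", "end", "n_windows", "pi_a", "pi_b", "ratio")]
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Call F_ST outlier sites
#'
#' Emits the windows/sites whose weighted F_ST exceeds a fixed threshold.
#' The threshold is a declared cutoff, not a p-value procedure, so no
#' multiple-testing correction applies.
#'
#' @param records Tibble from [windowed_fst()] (or any tibble with `chrom`,
#'   `pos`, `fst_weighted`).
#' @param fst_threshold Sites with `fst_weighted` strictly greater than this
#'   are flagged (default 0.5).
#' @return A tibble sorted by (chrom, pos): `chrom`, `pos` (1-based bp) and
#'   `fst`.
#' @export
call_fst_outliers <- function(records, fst_threshold = 0.5) {
  out <- records[!is.na(records$fst_weighted) &
                   records$fst_weighted > fst_threshold, , drop = FALSE]
  out <- tibble(chrom = out$chrom, pos = as.integer(out$pos),
                fst = out$fst_weighted)
  dplyr::arrange(out, .data$chrom, .data$pos)
}

#' Attach candidate flanking windows (and gene overlaps) to outlier sites
#'
#' For each outlier SNP, builds the candidate search window centred on the
#' marker: `[pos - flank, pos + flank)` in 0-based half-open coordinates
#' (100 kb total at the 50 kb default), clipped at the chromosome start.
#' When a gene table is supplied, genes whose interval intersects the flank
#' are listed.
#'
#' @param sites Tibble from [call_fst_outliers()].
#' @param flank Half-width of the candidate window in bp (default 50,000).
#' @param genes Optional gene tibble from [read_gff3_genes()].
#' @return `sites` with added columns `flank_start`, `flank_end`, and, when
#'   `genes` is given, a list-column `overlapping_genes` plus `n_genes`.
#' @export
extract_candidate_windows <- function(sites, flank = 50000, genes = NULL) {
  sites <- dplyr::arrange(as_tibble(sites), .data$chrom, .data$pos)
  sites$flank_start <- pmax(0L, as.integer(sites$pos - flank))
  sites$flank_end <- as.integer(sites$pos + flank)
  if (!is.null(genes)) {
    sites$overlapping_genes <- purrr::pmap(
      list(sites$chrom, sites$flank_start, sites$flank_end),
      function(ch, s, e) {
        hit <- genes$chrom == ch & genes$start < e & genes$end > s
        genes$gene_id[hit]
      }
    )
    sites$n_genes <- lengths(sites$overlapping_genes)
  }
  sites
}

#' Welch two-sample t-test on group-level window statistics
#'
#' Thin wrapper around the Welch (unequal-variance) t-test used to compare
#' genome-wide windowed statistics between breeding-history groups, treating
#' windows as independent observations. When both samples have zero variance
#' and equal means the test is degenerate and `t = 0`, `p = 1` by
#' convention.
#'
#' @param x,y Numeric samples (each of length >= 2, NA dropped).
#' @param statistic Optional label naming the statistic compared (carried
#'   into the output).
#' @return A one-row tibble: `statistic`, `mean_x`, `mean_y`, `t`, `df`,
#'   `p_value` (two-sided).
#' @export
welch_t_test <- function(x, y, statistic = NA_character_) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    abort("welch_t_test: each sample needs >= 2 non-missing values")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(tibble(statistic = statistic, mean_x = mean(x), mean_y = mean(y),
                    t = 0, df = length(x) + length(y) - 2, p_value = 1))
    }
    abort("welch_t_test: both samples are constant with different means")
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  tibble(
    statistic = statistic,
    mean_x = mean(x), mean_y = mean(y),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value
  )
}

#' Genome-wide averages of windowed statistics
#'
#' Averages windowed values across all windows in which they are defined;
#' windows with undefined Tajima's D (no segregating site) are excluded from
#' the D mean, never counted as zero.
#'
#' @param wins A window tibble from [windowed_pi()] and/or
#'   [windowed_tajima_d()] (any tibble with a `pi` and/or `tajima_d` column).
#' @return A one-row tibble with `n_windows` plus `mean_pi` and/or `mean_d`
#'   as available (`NA` if no window defines the statistic).
#' @export
genome_wide_summary <- function(wins) {
  if (nrow(wins) == 0) abort("genome_wide_summary: no windows")
  out <- tibble(n_windows = nrow(wins))
  if ("pi" %in% names(wins)) {
    out$mean_pi <- mean(wins$pi, na.rm = TRUE)
  }
  if ("tajima_d" %in% names(wins)) {
    d <- wins$tajima_d[!is.na(wins$tajima_d)]
    out$mean_d <- if (length(d)) mean(d) else NA_real_
    out$n_windows_d <- length(d)
  }
  out
}
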