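# Independent oracles: written from the textbook definitions, deliberately
# not sharing code paths with the package implementations they check.

# Brute-force windowed diversity: expand each site's dosages into explicit
# chromosome alleles, enumerate every chromosome pair, count mismatching
# pairs, divide by the number of pairs and the window length.
oracle_window_pi <- function(dosage_cols, window_size) {
  total <- 0
  for (col in dosage_cols) {
    col <- col[!is.na(col)]
    if (length(col) < 1) next
    alleles <- unlist(lapply(col, function(d) c(rep(1, d), rep(0, 2 - d))))
    n <- length(alleles)
    if (n < 2) next
    mismatches <- 0
    pairs <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        pairs <- pairs + 1
        if (alleles[i] != alleles[j]) mismatches <- mismatches + 1
      }
    }
    total <- total + mismatches / pairs
  }
  total / window_size
}

# Weir & Cockerham (1984) two-population components, transcribed literally
# from the published definitions with scalar arithmetic.
oracle_wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nC <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nC) * (s2 - (1 / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
    ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

# Welch statistic and Satterthwaite df from the textbook formulas.
oracle_welch <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Small panel builder used across tests.
toy_panel <- function(dosage, chrom = "Pv01", pos = NULL, ids = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(pos)) pos <- seq_len(ncol(dosage)) * 100L
  genotype_matrix(
    dosage,
    tibble::tibble(chrom = chrom, pos = pos, ref = "A", alt = "G"),
    sample_ids = ids %||% sprintf("s%d", seq_len(nrow(dosage)))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One directory of deterministic file fixtures per test run.
fixture_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "criollo-fixtures")
      make_fixture_suite(dir)
    }
    dir
  }
})
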