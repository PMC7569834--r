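#' Read a VCF into a filtered genotype matrix
#'
#' Parses a VCF (via \pkg{vcfR}), keeps biallelic SNP records only, and
#' applies the array-QC filters used to assemble the panel: sites with minor
#' allele frequency at or below `min_maf`, or with a missing-call fraction
#' above `max_missing`, are removed. MAF is computed on non-missing
#' chromosomes only. Dropped multiallelic/non-SNP record counts are reported
#' with a message.
#'
#' @param path Path to a VCF (4.x, GT field required; plain or gzipped).
#' @param min_maf Sites with MAF \eqn{\le} `min_maf` are removed. Default
#'   0.01, the panel's published filter.
#' @param max_missing Maximum tolerated fraction of missing calls per site.
#' @return A [genotype_matrix()] with sites sorted by (chrom, pos).
#' @export
read_vcf <- function(path, min_maf = 0.01, max_missing = 0.2) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (nrow(fix) == 0) abort("VCF contains no variant records")
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_drop <- sum(!snp)
  if (n_drop > 0) {
    inform(sprintf("read_vcf: dropped %d multiallelic/non-SNP record(s)", n_drop))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) abort("VCF has no GT field")
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  if (nrow(fix) == 0) abort("no biallelic SNP records survive parsing")
  dosage <- gt_to_dosage(gt)
  g <- genotype_matrix(
    t(dosage),
    tibble(
      chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
      ref = fix[, "REF"], alt = fix[, "ALT"]
    ),
    sample_ids = colnames(gt)
  )
  filter_sites(g, min_maf = min_maf, max_missing = max_missing)
}

# "0/0" style diploid GT strings -> alt-allele dosage; any missing allele -> NA
gt_to_dosage <- function(gt) {
  lv <- c(
    "0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
    "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L
  )
  out <- matrix(lv[gt], nrow = nrow(gt), dimnames = dimnames(gt))
  unknown <- !is.na(gt) & is.na(out)
  if (any(unknown)) {
    bad <- unique(gt[unknown])
    haploidish <- bad %in% c("0", "1", ".", "./.", ".|.")
    if (!all(haploidish)) {
      abort(paste0("cannot parse GT value(s): ", paste(bad, collapse = ", ")))
    }
  }
  out
}

#' Apply MAF and missingness filters to a genotype matrix
#'
#' @inheritParams read_vcf
#' @param g A [genotype_matrix()].
#' @return The filtered `genotype_matrix`; errors if no site survives.
#' @export
filter_sites <- function(g, min_maf = 0.01, max_missing = 0.2) {
  s <- allele_summary(g)
  keep <- !is.na(s$maf) & s$maf > min_maf & s$missingness <= max_missing
  n_rm <- sum(!keep)
  if (n_rm > 0) {
    inform(sprintf(
      "filter_sites: removed %d site(s) (MAF <= %g or missingness > %g)",
      n_rm, min_maf, max_missing
    ))
  }
  if (!any(keep)) abort("no sites survive filtering: empty panel")
  genotype_matrix(
    g$dosage[, keep, drop = FALSE],
    g$sites[keep, , drop = FALSE],
    g$sample_ids
  )
}

#' Write a genotype matrix as VCF 4.2
#'
#' Minimal plain-text VCF emitter (GT-only, unphased) so that panels round
#' trip through [read_vcf()] with dosages, positions and alleles preserved.
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  d <- g$dosage
  gt_strings <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gt_strings[d[ok] + 1L]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=criollo",
    paste0("##contig=<ID=", unique(g$sites$chrom), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", g$sample_ids
    ), collapse = "\t")
  )
  body <- paste(
    g$sites$chrom, g$sites$pos, ".", g$sites$ref, g$sites$alt,
    ".", "PASS", ".", "GT",
    apply(gt, 2, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sample-to-group population map
#'
#' @param path TSV with header columns `sample_id`, `group`, `is_reference`.
#'   `is_reference` flags the non-fixing reference line used to anchor the
#'   15N natural-abundance calculation.
#' @return A tibble with columns `sample_id` (character), `group` (character)
#'   and `is_reference` (logical). Duplicate sample ids are an error; group
#'   labels outside the usual breeding-history set are allowed but reported.
#' @export
read_population_map <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE)
  needed <- c("sample_id", "group", "is_reference")
  if (!all(needed %in% names(m))) {
    abort(paste0("population map needs columns: ", paste(needed, collapse = ", ")))
  }
  m <- dplyr::transmute(
    m,
    sample_id = as.character(.data$sample_id),
    group = as.character(.data$group),
    is_reference = as.logical(.data$is_reference)
  )
  if (anyDuplicated(m$sample_id)) {
    dup <- unique(m$sample_id[duplicated(m$sample_id)])
    abort(paste0("duplicated sample_id in population map: ", paste(dup, collapse = ", ")))
  }
  known <- c("LANDRACE", "PPB", "CONVENTIONAL", "CHECK", "ADMIXED")
  odd <- setdiff(unique(m$group), known)
  if (length(odd)) {
    inform(paste0("read_population_map: unrecognised group label(s): ",
                  paste(odd, collapse = ", ")))
  }
  m
}

#' Write genomic intervals as BED
#'
#' Intervals are 0-based half-open throughout the package, matching the BED
#' convention, so coordinates are written as-is. Any extra numeric columns
#' are carried along as score columns.
#'
#' @param intervals Data frame with `chrom`, `start`, `end` plus optional
#'   score columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  intervals <- as_tibble(intervals)
  needed <- c("chrom", "start", "end")
  if (!all(needed %in% names(intervals))) {
    abort("`intervals` needs columns chrom, start, end")
  }
  if (nrow(intervals) > 0 && any(intervals$start >= intervals$end)) {
    abort("intervals must satisfy 0 <= start < end")
  }
  intervals <- dplyr::arrange(intervals, .data$chrom, .data$start)
  intervals$start <- format(intervals$start, scientific = FALSE, trim = TRUE)
  intervals$end <- format(intervals$end, scientific = FALSE, trim = TRUE)
  extra <- setdiff(names(intervals), needed)
  cols <- c(needed, extra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  if (nrow(intervals) > 0) {
    lines <- do.call(paste, c(unname(as.list(intervals[cols])), sep = "\t"))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a BED file written by [write_bed()]
#'
#' @param path Path to a BED (3+score) file; lines starting with `#` are
#'   treated as the header.
#' @return A tibble with `chrom`, `start`, `end` and any score columns.
#' @export
read_bed <- function(path) {
  first <- readLines(path, n = 1)
  cols <- NULL
  if (length(first) && startsWith(first, "#")) {
    cols <- strsplit(sub("^#", "", first), "\t")[[1]]
  }
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_names = cols %||% FALSE)
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer())
    return(out)
  }
  if (is.null(cols)) names(out)[1:3] <- c("chrom", "start", "end")
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  out
}

#' Read gene intervals from a GFF3 file
#'
#' Extracts features of type `gene` and converts their 1-based inclusive GFF
#' coordinates to the package's 0-based half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble sorted by (chrom, start): `chrom`, `start`, `end`
#'   (0-based half-open) and `gene_id`.
#' @export
read_gff3_genes <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("read_gff3_genes requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  gene_id = character()))
  }
  ids <- gr$ID
  if (is.null(ids)) ids <- paste0("gene", seq_along(gr))
  out <- tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    gene_id = as.character(ids)
  )
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Read a per-plot isotope measurement table
#'
#' @param path TSV with header columns `genotype_id`, `group`, `environment`,
#'   `plot`, `delta15N`, `delta13C`, `is_reference`. `delta15N`/`delta13C`
#'   are per-mil values from mass spectrometry of seed tissue.
#' @return A tibble of per-plot records. Non-negative `delta13C` values are
#'   physiologically implausible for plant tissue and trigger a warning (not
#'   an error).
#' @export
read_isotope_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  needed <- c("genotype_id", "group", "environment", "plot",
              "delta15N", "delta13C", "is_reference")
  if (!all(needed %in% names(x))) {
    abort(paste0("isotope table needs columns: ", paste(needed, collapse = ", ")))
  }
  x$is_reference <- as.logical(x$is_reference)
  if (any(x$delta13C >= 0, na.rm = TRUE)) {
    warn("read_isotope_table: delta13C >= 0 permil is implausible for plant tissue")
  }
  x
}
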