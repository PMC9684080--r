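## Plain-text readers and writers for the formats the pipeline exchanges.
## Coordinates are 0-based half-open (BED convention) throughout.

#' Write / read fragment records as BED3+1
#'
#' Columns: chrom, start, end, sample. 0-based half-open, tab-separated, no
#' header.
#'
#' @param fragments Data frame with chrom, start, end, sample.
#' @param path File path.
#' @return `read_fragments` returns the data frame; writers return the path
#'   invisibly.
#' @export
write_fragments <- function(fragments, path) {
  stopifnot(all(c("chrom", "start", "end", "sample") %in% names(fragments)))
  utils::write.table(fragments[, c("chrom", "start", "end", "sample")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments
#' @export
read_fragments <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "sample"),
                          colClasses = c("character", "integer", "integer", "character"))
  df
}

#' Write / read SNV allele-count tables
#'
#' Tab-separated with header: chrom, pos (1-based), ref, alt, sample,
#' ref_count, alt_count, multiplicity, copy_number, clonal_flag.
#'
#' @param alleles Data frame as produced by [simulate_allele_counts()].
#' @param path File path.
#' @export
write_allele_counts <- function(alleles, path) {
  cols <- c("chrom", "pos", "ref", "alt", "sample", "ref_count", "alt_count",
            "multiplicity", "copy_number", "clonal_flag")
  stopifnot(all(cols %in% names(alleles)))
  utils::write.table(alleles[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_allele_counts
#' @export
read_allele_counts <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write / read a peak table (BED6 + count matrix)
#'
#' The intervals go to `<prefix>_peaks.bed` (chrom, start, end, peak_id,
#' score 0, strand "."), the counts to `<prefix>_counts.tsv` (peaks x
#' samples, with header and peak_id row names).
#'
#' @param peak_table A `peak_table` object (or a list with `peaks` and
#'   `counts`).
#' @param prefix Path prefix.
#' @export
write_peak_table <- function(peak_table, prefix) {
  pk <- peak_table$peaks
  bed <- data.frame(pk$chrom, pk$start, pk$end, pk$peak_id, 0L, ".")
  utils::write.table(bed, paste0(prefix, "_peaks.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  counts <- data.frame(peak_id = rownames(peak_table$counts),
                       peak_table$counts, check.names = FALSE)
  utils::write.table(counts, paste0(prefix, "_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(prefix) {
  bed <- utils::read.table(paste0(prefix, "_peaks.bed"), sep = "\t",
                           col.names = c("chrom", "start", "end", "peak_id",
                                         "score", "strand"),
                           stringsAsFactors = FALSE)
  counts <- utils::read.table(paste0(prefix, "_counts.tsv"), sep = "\t",
                              header = TRUE, check.names = FALSE,
                              stringsAsFactors = FALSE)
  m <- as.matrix(counts[, -1, drop = FALSE])
  rownames(m) <- counts$peak_id
  list(peaks = bed[, c("chrom", "start", "end", "peak_id")], counts = m)
}

#' Write / read binned log2-ratio tracks as BED4
#'
#' Columns: contig, start, end, log2ratio; one file per sample or a long
#' table with a sample column when `long = TRUE`.
#'
#' @param bins Data frame with contig, start, end, log2ratio (and sample for
#'   long format).
#' @param path File path.
#' @param long Include the sample column.
#' @export
write_bins <- function(bins, path, long = "sample" %in% names(bins)) {
  cols <- if (long) c("sample", "contig", "start", "end", "log2ratio") else
    c("contig", "start", "end", "log2ratio")
  utils::write.table(bins[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_bins
#' @export
read_bins <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write / read a cohort configuration as structured text (YAML)
#'
#' @param config A [cohort_config()] object.
#' @param path File path.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  yaml::write_yaml(unclass(config), path, precision = 12)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(cohort_config, vals)
}

#' Write ground truth tables (one TSV per effect class)
#'
#' Writes `purity.tsv`, `segments.tsv` and, if supplied, `peaks.tsv` and
#' `tf_effects.tsv` into a directory.
#'
#' @param truth Ground-truth list from a `gland_cohort`.
#' @param dir Output directory (created if needed).
#' @param peak_truth,tf_truth Optional truth tables from the peak and TF
#'   generators.
#' @export
write_ground_truth <- function(truth, dir, peak_truth = NULL, tf_truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(data.frame(sample = names(truth$purity),
                                purity = as.numeric(truth$purity)),
                     file.path(dir, "purity.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth$segments, file.path(dir, "segments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(peak_truth)) {
    utils::write.table(peak_truth, file.path(dir, "peaks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(tf_truth)) {
    utils::write.table(data.frame(tf = names(tf_truth), effect = as.numeric(tf_truth)),
                       file.path(dir, "tf_effects.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
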