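## Genome-wide TF binding-site accessibility signatures.
##
## For every TF-site set, insertions (Tn5 cut sites) around site centres are
## tabulated into an insertion-size x distance matrix, normalized per size
## bin by the genome-wide insertion count of that size, and
## background-corrected using the outer flanks. The tumour-normal difference
## integrated over the nucleosome-free central block is a per-sample scalar
## TF signal, which is regressed on purity and TSS-enrichment covariates;
## the per-patient purity coefficients form the substrate for clustering.

#' Build a normalized insertion-size x distance matrix around TF sites
#'
#' Distances are measured from the site centre, orientation-flipped for
#' minus-strand sites. Each row (5-bp insertion-size bin) is divided by the
#' genome-wide insertion count of that size bin, then the mean of the
#' background flank (750-1,000 bp on both sides) is subtracted per row.
#'
#' @param fragments Fragment records (chrom, start, end) of one sample.
#' @param sites Data frame chrom, center, strand for one TF-site set.
#' @param flank Half-window around centres in bp.
#' @param size_range Insertion sizes tabulated (inclusive).
#' @param size_bin Size bin width in bp.
#' @param genome_size_counts Optional named per-size-bin genome-wide
#'   insertion counts; computed from `fragments` when NULL.
#' @return Object of class `insertion_matrix`: a numeric matrix (size bins x
#'   distances) with attributes `size_breaks` and `distances`.
#' @export
build_insertion_matrix <- function(fragments, sites, flank = 1000,
                                   size_range = c(20, 620), size_bin = 5,
                                   genome_size_counts = NULL) {
  stopifnot(nrow(sites) >= 1)
  size_breaks <- seq(size_range[1], size_range[2] + size_bin, by = size_bin)
  n_rows <- length(size_breaks) - 1L
  dists <- -flank:flank
  M <- matrix(0, n_rows, length(dists),
              dimnames = list(sprintf("[%d,%d)", size_breaks[-length(size_breaks)],
                                      size_breaks[-1]), dists))
  if (nrow(fragments) == 0) {
    warning("empty cut data: returning zero matrix")
    out <- M
    attr(out, "size_breaks") <- size_breaks
    attr(out, "distances") <- dists
    class(out) <- c("insertion_matrix", class(out))
    return(out)
  }
  size <- fragments$end - fragments$start
  pos <- c(fragments$start - 4L, fragments$end + 5L) ## both Tn5 cut sites
  chrom <- rep(fragments$chrom, 2L)
  sz <- rep(size, 2L)
  in_range <- sz >= size_range[1] & sz <= size_range[2]
  row_i <- findInterval(sz, size_breaks, rightmost.closed = TRUE)
  if (is.null(genome_size_counts)) {
    genome_size_counts <- tabulate(row_i[in_range], nbins = n_rows)
  }
  for (ct in unique(sites$chrom)) {
    s <- sites[sites$chrom == ct, ]
    o <- order(s$center)
    cent <- s$center[o]; strd <- s$strand[o]
    sel <- which(chrom == ct & in_range)
    if (!length(sel)) next
    near <- findInterval(pos[sel], cent - 0.5) ## nearest centre index below
    for (shift in c(0L, 1L)) {
      idx <- near + shift
      ok <- idx >= 1L & idx <= length(cent)
      d <- pos[sel[ok]] - cent[idx[ok]]
      flip <- strd[idx[ok]] == "-"
      d[flip] <- -d[flip]
      keep <- abs(d) <= flank
      if (!any(keep)) next
      ri <- row_i[sel[ok]][keep]
      ci <- d[keep] + flank + 1L
      tab <- table(factor(ri, levels = seq_len(n_rows)),
                   factor(ci, levels = seq_along(dists)))
      M <- M + as.matrix(tab)
    }
  }
  ## per-size normalization against the genome-wide insertion count
  norm <- ifelse(genome_size_counts > 0, genome_size_counts, NA_real_)
  M <- M / norm
  M[is.na(M)] <- 0
  ## flank background subtraction per size bin
  bg_cols <- abs(dists) >= 750 & abs(dists) <= 1000
  M <- M - rowMeans(M[, bg_cols, drop = FALSE])
  attr(M, "size_breaks") <- size_breaks
  attr(M, "distances") <- dists
  class(M) <- c("insertion_matrix", class(M))
  M
}

#' Read-weighted pooled insertion matrix
#'
#' @param matrices List of `insertion_matrix` objects on identical grids.
#' @param weights Per-matrix weights (e.g. sample read totals).
#' @return Pooled `insertion_matrix`.
#' @export
pool_insertion_matrices <- function(matrices, weights = rep(1, length(matrices))) {
  stopifnot(length(matrices) >= 1, length(weights) == length(matrices))
  ref <- matrices[[1]]
  out <- Reduce(`+`, Map(function(m, w) {
    stopifnot(identical(dim(m), dim(ref)))
    unclass(m) * w
  }, matrices, weights)) / sum(weights)
  attributes(out) <- attributes(ref)
  out
}

#' Differential TF signal of a sample versus the pooled normal
#'
#' Sum of (sample - pool) over insertion sizes within `size_window` and
#' distances within `dist_window` --- the nucleosome-free central block of
#' the footprint.
#'
#' @param sample_matrix,pool_matrix `insertion_matrix` objects on identical
#'   grids.
#' @param size_window Insertion-size integration window (bp).
#' @param dist_window Distance integration window (bp).
#' @return Scalar differential signal (0 for a sample identical to the
#'   pool).
#' @export
differential_signal <- function(sample_matrix, pool_matrix,
                                size_window = c(25, 120),
                                dist_window = c(-100, 100)) {
  sb <- attr(sample_matrix, "size_breaks")
  ds <- attr(sample_matrix, "distances")
  if (!identical(sb, attr(pool_matrix, "size_breaks")) ||
      !identical(ds, attr(pool_matrix, "distances"))) {
    stop("insertion matrices are on different grids")
  }
  rows <- sb[-length(sb)] >= size_window[1] & sb[-1] - 1 <= size_window[2]
  cols <- ds >= dist_window[1] & ds <= dist_window[2]
  sum(unclass(sample_matrix)[rows, cols] - unclass(pool_matrix)[rows, cols])
}

#' Regress TF signals on purity and TSS-enrichment covariates
#'
#' Weighted least squares of the per-sample differential signal on
#' `tsse * tsse_nf + purity:group`, where `group` is patient (default) or
#' region, `tsse` and `tsse_nf` are TSS-enrichment differences versus the
#' pooled normal, and observations are weighted by the square root of the
#' sample read count. The per-group purity-interaction coefficients are the
#' group-specific TF summary.
#'
#' @param signals Data frame with columns signal, tsse, tsse_nf, purity,
#'   reads, and the grouping column.
#' @param group Name of the grouping column (`"patient"` or `"region"`).
#' @return Data frame group, coefficient, se, p (one row per group level).
#' @export
regress_tf_signal <- function(signals, group = "patient") {
  need <- c("signal", "tsse", "tsse_nf", "purity", "reads", group)
  stopifnot(all(need %in% names(signals)))
  signals[[group]] <- as.factor(signals[[group]])
  fml <- stats::as.formula(paste("signal ~ tsse * tsse_nf + purity:", group))
  fit <- stats::lm(fml, data = signals, weights = sqrt(signals$reads))
  cf <- summary(fit)$coefficients
  sel <- grep(paste0("^purity:", group), rownames(cf))
  lev <- sub(paste0("^purity:", group), "", rownames(cf)[sel])
  data.frame(group = lev, coefficient = cf[sel, 1], se = cf[sel, 2],
             p = cf[sel, 4], row.names = NULL, stringsAsFactors = FALSE)
}

#' Cluster per-patient TF coefficients
#'
#' Selects the `top_k` TFs most frequently showing a significant purity
#' association, then hierarchically clusters TFs on their per-patient
#' coefficient profiles (Euclidean distance, complete linkage).
#'
#' @param coef_matrix Matrix patients x TFs of purity-interaction
#'   coefficients.
#' @param p_matrix Matrix of the matching p-values (used for TF selection);
#'   NULL selects by coefficient magnitude instead.
#' @param top_k Number of TFs to keep.
#' @param k_clusters Number of flat clusters to cut.
#' @param alpha Significance level for counting.
#' @return List: `tree` (hclust over TFs), `clusters` (named cluster
#'   labels), `tfs` (selected TFs).
#' @export
cluster_tf_coefficients <- function(coef_matrix, p_matrix = NULL, top_k = 150,
                                    k_clusters = 3, alpha = 0.05) {
  stopifnot(is.matrix(coef_matrix))
  score <- if (!is.null(p_matrix)) {
    colSums(p_matrix < alpha, na.rm = TRUE)
  } else {
    colMeans(abs(coef_matrix), na.rm = TRUE)
  }
  if (top_k > ncol(coef_matrix)) {
    message(sprintf("top_k = %d exceeds available TFs (%d); using all",
                    top_k, ncol(coef_matrix)))
    top_k <- ncol(coef_matrix)
  }
  tfs <- colnames(coef_matrix)[order(-score)[seq_len(top_k)]]
  sub <- coef_matrix[, tfs, drop = FALSE]
  tree <- stats::hclust(stats::dist(t(sub)), method = "complete")
  k_clusters <- min(k_clusters, length(tfs))
  clusters <- stats::cutree(tree, k = k_clusters)
  list(tree = tree, clusters = clusters, tfs = tfs)
}
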