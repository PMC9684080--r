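## Mutational signature exposures and region-stratified activities.
##
## Exposures of a fixed set of 96-channel signatures are fitted to mutation
## catalogues by non-negative L1-regularized least squares (coordinate
## descent). Patients are clustered on the cosine distance between their
## exposure vectors; signature activities in genomic region classes are
## estimated by repeated jackknife subsampling with trinucleotide-content
## normalization of the region catalogues.

#' Fit signature exposures by non-negative L1-regularized regression
#'
#' Minimizes the count-scale objective
#' `||X - t(S) E||^2 + lambda * ||E||_1` subject to `E >= 0` by cyclic
#' coordinate descent, where `X` is the 96-channel catalogue and `S` the
#' k x 96 signature matrix. Internally the problem is solved on the
#' frequency scale (`x = X / N`, `N` the catalogue size) for conditioning;
#' dividing the count-scale objective by `N^2` shows the equivalent
#' frequency-scale penalty is `lambda / N`, which is what is applied.
#' Exposures are reported normalized to sum 1.
#'
#' @param catalogue Integer or numeric vector of 96 channel counts.
#' @param signatures Matrix k x 96, rows summing to 1.
#' @param lambda L1 penalty on the count scale (>= 0); 0 gives non-negative
#'   least squares.
#' @param tol,max_iter Convergence controls.
#' @return List: `exposures` (normalized, sum 1), `exposures_raw`,
#'   `fitted` (reconstructed spectrum), `residual` (L2 norm), `empty`
#'   (TRUE for an all-zero catalogue, in which case exposures are all 0).
#' @export
fit_exposures <- function(catalogue, signatures, lambda = 0.025,
                          tol = 1e-12, max_iter = 2000) {
  stopifnot(length(catalogue) == ncol(signatures), lambda >= 0)
  k <- nrow(signatures)
  nm <- rownames(signatures)
  if (sum(catalogue) == 0) {
    z <- stats::setNames(rep(0, k), nm)
    return(list(exposures = z, exposures_raw = z,
                fitted = stats::setNames(rep(0, 96), colnames(signatures)),
                residual = 0, empty = TRUE))
  }
  N <- sum(catalogue)
  x <- catalogue / N
  lambda <- lambda / N ## frequency-scale equivalent of the count-scale penalty
  A <- t(signatures) ## 96 x k
  AtA <- crossprod(A)
  Atx <- crossprod(A, x)
  e <- rep(0, k)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(k)) {
      rj <- Atx[j] - sum(AtA[j, -j] * e[-j])
      new <- max(0, (rj - lambda / 2) / AtA[j, j])
      delta <- max(delta, abs(new - e[j]))
      e[j] <- new
    }
    if (delta < tol) break
  }
  names(e) <- nm
  fitted <- as.numeric(A %*% e)
  norm <- if (sum(e) > 0) e / sum(e) else e
  list(exposures = norm, exposures_raw = e,
       fitted = stats::setNames(fitted, colnames(signatures)),
       residual = sqrt(sum((x - fitted)^2)), empty = FALSE)
}

#' Normalize a catalogue for region-specific trinucleotide content
#'
#' Each channel count is multiplied by the genome-wide frequency of its
#' trinucleotide context divided by the region-specific frequency, removing
#' the compositional bias of the region before exposure fitting.
#'
#' @param catalogue 96-channel count vector.
#' @param region_content,genome_content Named frequency vectors over the 32
#'   trinucleotide contexts (must be positive wherever mutations are
#'   observed).
#' @return Normalized numeric 96-vector (same names).
#' @export
trinucleotide_normalize <- function(catalogue, region_content, genome_content) {
  ctx <- sbs96_contexts()
  miss <- setdiff(ctx, intersect(names(region_content), names(genome_content)))
  if (length(miss)) stop(sprintf("content table missing contexts: %s",
                                 paste(unique(miss), collapse = ", ")))
  rf <- as.numeric(region_content[ctx])
  gf <- as.numeric(genome_content[ctx])
  bad <- rf <= 0 & catalogue > 0
  if (any(bad)) {
    stop(sprintf("zero region frequency for context %s with non-zero counts",
                 ctx[which(bad)[1]]))
  }
  out <- as.numeric(catalogue) * ifelse(rf > 0, gf / rf, 0)
  stats::setNames(out, names(catalogue))
}

#' Cluster patients on cosine distance between exposures
#'
#' Computes the pairwise matrix of 1 minus the cosine similarity of patient
#' exposure vectors and applies k-means to its rows (fixed seed, multiple
#' restarts).
#'
#' @param exposures Matrix patients x signatures.
#' @param k Number of clusters (>= 1).
#' @param seed Seed for k-means restarts.
#' @param n_start k-means restarts.
#' @return Named integer vector of cluster labels.
#' @export
cluster_patients <- function(exposures, k = 6, seed = 1L, n_start = 25) {
  if (k < 1) stop("k must be >= 1")
  stopifnot(k <= nrow(exposures))
  n <- nrow(exposures)
  D <- matrix(0, n, n, dimnames = list(rownames(exposures), rownames(exposures)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      D[i, j] <- 1 - cosine_similarity(exposures[i, ], exposures[j, ])
    }
  }
  km <- with_seed(seed, stats::kmeans(D, centers = k, nstart = n_start))
  stats::setNames(km$cluster, rownames(exposures))
}

#' Jackknifed signature activities per genomic region class
#'
#' For each patient cluster with at least `min_cluster` samples, repeats
#' `n_iter` times: draw a random `keep_frac` of the cluster's samples,
#' aggregate their catalogues per region class, normalize for region
#' trinucleotide content, and fit exposures. Reported per (cluster, region,
#' signature): the jackknife mean and 2.5/97.5 percentiles of the exposure,
#' and the activity --- exposure scaled by the region's aggregated mutation
#' count and divided by the region size.
#'
#' @param catalogues Data frame with columns sample, cluster, region_class
#'   and the 96 channel columns (as from [simulate_region_catalogues()]).
#' @param signatures Matrix k x 96.
#' @param region_content Named list region_class -> 32-context frequencies.
#' @param genome_content 32-context frequency vector.
#' @param region_sizes Named vector of region sizes (default 1 for all:
#'   activities are then per-genome rather than per-bp).
#' @param n_iter,keep_frac Jackknife controls.
#' @param lambda L1 penalty for the fits.
#' @param min_cluster Minimum samples per cluster; smaller clusters are
#'   skipped with a message.
#' @param exclude_clusters Cluster labels excluded from estimation (rare,
#'   highly distinct clusters would otherwise bias the group estimates).
#' @param seed Seed.
#' @return Data frame cluster, region_class, signature, exposure_mean,
#'   exposure_lo, exposure_hi, activity_mean, activity_lo, activity_hi.
#' @export
jackknife_activities <- function(catalogues, signatures, region_content = NULL,
                                 genome_content = synthetic_trinucleotide_content(),
                                 region_sizes = NULL, n_iter = 100,
                                 keep_frac = 0.9, lambda = 0.025,
                                 min_cluster = 3, exclude_clusters = NULL,
                                 seed = 1L) {
  ch <- sbs96_channels()
  stopifnot(all(ch %in% names(catalogues)))
  classes <- unique(catalogues$region_class)
  if (is.null(region_content)) {
    region_content <- stats::setNames(rep(list(genome_content), length(classes)), classes)
  }
  if (is.null(region_sizes)) {
    region_sizes <- stats::setNames(rep(1, length(classes)), classes)
  }
  out <- list()
  for (cl in setdiff(unique(catalogues$cluster), exclude_clusters)) {
    cc <- catalogues[catalogues$cluster == cl, ]
    samples <- unique(cc$sample)
    if (length(samples) < min_cluster) {
      message(sprintf("cluster %s has %d < %d samples; skipped",
                      cl, length(samples), min_cluster))
      next
    }
    n_keep <- max(1L, ceiling(keep_frac * length(samples)))
    expo <- array(NA_real_, c(n_iter, length(classes), nrow(signatures)),
                  dimnames = list(NULL, classes, rownames(signatures)))
    act <- expo
    with_seed(stage_seed(seed, paste0("jk_", cl)), {
      for (it in seq_len(n_iter)) {
        keep <- sample(samples, n_keep)
        sub <- cc[cc$sample %in% keep, ]
        for (rc in classes) {
          cat96 <- colSums(as.matrix(sub[sub$region_class == rc, ch, drop = FALSE]))
          total <- sum(cat96)
          norm <- trinucleotide_normalize(cat96, region_content[[rc]], genome_content)
          fit <- fit_exposures(norm, signatures, lambda = lambda)
          expo[it, rc, ] <- fit$exposures
          act[it, rc, ] <- fit$exposures * total / region_sizes[[rc]]
        }
      }
    })
    for (rc in classes) {
      for (sg in rownames(signatures)) {
        e <- expo[, rc, sg]; a <- act[, rc, sg]
        out[[length(out) + 1L]] <- data.frame(
          cluster = cl, region_class = rc, signature = sg,
          exposure_mean = mean(e),
          exposure_lo = unname(stats::quantile(e, 0.025)),
          exposure_hi = unname(stats::quantile(e, 0.975)),
          activity_mean = mean(a),
          activity_lo = unname(stats::quantile(a, 0.025)),
          activity_hi = unname(stats::quantile(a, 0.975)),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Signature attribution of a mutation subset
#'
#' Fits exposures to a subset catalogue (e.g. mutations predicted to alter
#' TF binding affinity) and reports the cosine similarity between the
#' subset's reconstructed spectrum and the spectrum implied by the
#' background exposures.
#'
#' @param subset_catalogue 96-channel counts of the subset.
#' @param signatures Matrix k x 96.
#' @param background_exposures Exposure vector (length k) of the background
#'   mutation set.
#' @param lambda L1 penalty.
#' @return List: `exposures`, `cosine` (similarity to the background
#'   spectrum); both NA for an empty subset.
#' @export
attribute_mutation_subset <- function(subset_catalogue, signatures,
                                      background_exposures, lambda = 0.025) {
  if (sum(subset_catalogue) == 0) {
    return(list(exposures = NA, cosine = NA_real_))
  }
  fit <- fit_exposures(subset_catalogue, signatures, lambda = lambda)
  recon <- as.numeric(t(signatures) %*% fit$exposures)
  bg <- as.numeric(t(signatures) %*%
                     (background_exposures / sum(background_exposures)))
  list(exposures = fit$exposures, cosine = cosine_similarity(recon, bg))
}
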