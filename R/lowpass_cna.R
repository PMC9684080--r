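## Integer copy number from low-pass WGS: joint segmentation of binned log2
## ratios across the samples of a patient, followed by a purity / integer
## copy-number grid fit.
##
## The fit inverts the standard relation between the (median-centred) log2
## coverage ratio r of a bin and its underlying integer state n at purity
## rho and tumour ploidy psi_t (gamma = 1, as appropriate for sequencing
## data):
##
##   r = log2( (2(1-rho) + rho n) / (2(1-rho) + rho psi_t) )
##
## For each candidate purity, the continuous copy number of every segment is
## computed and the length-weighted sum of squared distances to the nearest
## non-negative integer is the goodness of fit; purity estimates are local
## minima of that curve.

#' Jointly segment binned log2-ratio tracks across samples
#'
#' Breakpoints are shared across all samples of a patient and minimize the
#' summed within-segment squared error over samples plus `penalty` per
#' additional segment. Exact dynamic programming is used per contig up to
#' `max_dp_bins` bins; beyond that, greedy binary segmentation with the same
#' cost.
#'
#' @param bins Long data frame with sample, contig, start, end, log2ratio;
#'   every sample must cover the identical bin grid.
#' @param penalty Cost of introducing one breakpoint (same units as squared
#'   log2 ratio summed over samples and bins).
#' @param max_dp_bins Largest per-contig bin count solved exactly.
#' @return Object of class `segment_set`: `segments` (data frame contig,
#'   start, end, n_bins) and `means` (matrix segments x samples).
#' @export
segment_joint <- function(bins, penalty = 10, max_dp_bins = 1000) {
  stopifnot(all(c("sample", "contig", "start", "end", "log2ratio") %in% names(bins)))
  samples <- unique(bins$sample)
  key <- paste(bins$contig, bins$start)
  grids <- split(key, bins$sample)
  ref <- grids[[1]]
  if (!all(vapply(grids, function(g) identical(sort(g), sort(ref)), logical(1)))) {
    stop("inconsistent bin grids across samples")
  }
  seg_rows <- list(); mean_rows <- list()
  for (ct in unique(bins$contig)) {
    b <- bins[bins$contig == ct, ]
    b <- b[order(b$sample, b$start), ]
    starts <- sort(unique(b$start))
    X <- matrix(b$log2ratio[order(match(b$sample, samples), b$start)],
                nrow = length(starts), ncol = length(samples),
                dimnames = list(NULL, samples))
    ends <- sort(unique(b$end))
    cuts <- segment_breaks(X, penalty, max_dp_bins)
    bounds <- c(0L, cuts, nrow(X)) ## segment i spans bins bounds[i]+1..bounds[i+1]
    for (i in seq_len(length(bounds) - 1L)) {
      lo <- bounds[i] + 1L; hi <- bounds[i + 1L]
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        contig = ct, start = starts[lo], end = ends[hi], n_bins = hi - lo + 1L,
        stringsAsFactors = FALSE)
      mean_rows[[length(mean_rows) + 1L]] <- colMeans(X[lo:hi, , drop = FALSE])
    }
  }
  segments <- do.call(rbind, seg_rows)
  means <- do.call(rbind, mean_rows)
  rownames(means) <- sprintf("%s:%d-%d", segments$contig, segments$start, segments$end)
  structure(list(segments = segments, means = means), class = "segment_set")
}

## internal: breakpoints (bin indices after which a break occurs) for one
## contig; X is bins x samples
segment_breaks <- function(X, penalty, max_dp_bins) {
  n <- nrow(X)
  if (n <= 1) return(integer(0))
  cs <- apply(X, 2, cumsum)
  cs2 <- apply(X^2, 2, cumsum)
  cs <- rbind(0, cs); cs2 <- rbind(0, cs2)
  segcost <- function(i, j) { ## bins i..j inclusive, summed over samples
    s <- cs[j + 1L, ] - cs[i, ]
    s2 <- cs2[j + 1L, ] - cs2[i, ]
    sum(s2 - s^2 / (j - i + 1L))
  }
  if (n <= max_dp_bins) {
    ## exact DP: F[j] = min cost of segmenting bins 1..j
    F <- c(0, rep(Inf, n))
    prev <- integer(n)
    for (j in seq_len(n)) {
      for (i in seq_len(j)) {
        cand <- F[i] + segcost(i, j) + if (i > 1L) penalty else 0
        if (cand < F[j + 1L]) { F[j + 1L] <- cand; prev[j] <- i - 1L }
      }
    }
    cuts <- integer(0); j <- n
    while (j > 0L) { i <- prev[j]; if (i > 0L) cuts <- c(i, cuts); j <- i }
    cuts
  } else {
    ## greedy binary segmentation with the same cost structure
    split_rec <- function(lo, hi) {
      if (hi - lo < 1L) return(integer(0))
      base <- segcost(lo, hi)
      best_gain <- 0; best_k <- 0L
      for (k in lo:(hi - 1L)) {
        gain <- base - segcost(lo, k) - segcost(k + 1L, hi) - penalty
        if (gain > best_gain) { best_gain <- gain; best_k <- k }
      }
      if (best_k == 0L) return(integer(0))
      c(split_rec(lo, best_k), best_k, split_rec(best_k + 1L, hi))
    }
    split_rec(1L, n)
  }
}

#' Continuous copy number of a bin or segment
#'
#' Inverts the log2-ratio relation at purity `rho` and tumour ploidy
#' `psi_t`: `(2^r * (2(1-rho) + rho * psi_t) - 2(1-rho)) / rho`.
#'
#' @param r Log2 ratio (median-centred).
#' @param rho Purity in `(0, 1]`.
#' @param psi_t Tumour ploidy.
#' @return Continuous copy number (may be negative for deep losses at wrong
#'   purity; integer assignment clamps at 0).
#' @export
continuous_cn <- function(r, rho, psi_t) {
  if (any(rho <= 0)) stop("continuous copy number undefined at rho = 0")
  (2^r * (2 * (1 - rho) + rho * psi_t) - 2 * (1 - rho)) / rho
}

#' Fit purity and integer copy number to segment means by grid search
#'
#' For each candidate purity on a grid over `[0.1, 1]`, segment-level
#' continuous copy numbers are computed and scored by the length-weighted
#' sum of squared differences to the nearest non-negative integer. Purity
#' candidates are local minima of this curve (strictly lower than both grid
#' neighbours); the global best local minimum is chosen, with ties broken
#' toward higher purity. If no local minimum exists (e.g. a flat diploid
#' genome), purity is set to 1. Negative integer states are clamped to 0.
#'
#' Because the input tracks are median-centred, a genome whose gains and
#' losses are unbalanced leaves a small residual offset in the log2 ratios.
#' Before scoring, the fit therefore recentres the track on its modal
#' segment mean (length-weighted kernel density mode), which corresponds to
#' the ploidy state; the recentring shift is bounded by `recenter_range` so
#' it can never relabel whole copy-number states.
#'
#' @param seg_means Numeric vector of per-segment mean log2 ratios for one
#'   sample.
#' @param seg_lengths Segment lengths in bins (weights).
#' @param psi_t Integer tumour ploidy (from deep WGS or ground truth).
#' @param rho_step Grid step.
#' @param rho_range Purity search range.
#' @param recenter_range Half-width of the additive log2-ratio recentring
#'   search (0 disables it); kept well below log2(3/2) so recentring cannot
#'   relabel whole copy-number states.
#' @return Object of class `cn_fit`: `rho_hat`, `gof` (data frame rho, gof),
#'   `cn_cont`, `cn_int`, `local_minima`, `delta_hat`.
#' @export
fit_purity_cn <- function(seg_means, seg_lengths, psi_t, rho_step = 0.01,
                          rho_range = c(0.1, 1), recenter_range = 0.15) {
  if (length(seg_means) == 0) stop("empty segment set")
  stopifnot(length(seg_means) == length(seg_lengths),
            psi_t == round(psi_t), psi_t >= 1)
  grid <- seq(rho_range[1], rho_range[2], by = rho_step)
  delta_hat <- 0
  if (recenter_range > 0 && length(seg_means) > 1 &&
      stats::sd(seg_means) > 1e-12) {
    dens <- stats::density(seg_means, weights = seg_lengths / sum(seg_lengths),
                           bw = 0.02)
    mode_r <- dens$x[which.max(dens$y)]
    near <- abs(seg_means - mode_r) < 0.04
    delta_hat <- -stats::weighted.mean(seg_means[near], seg_lengths[near])
    delta_hat <- max(-recenter_range, min(recenter_range, delta_hat))
  }
  r <- seg_means + delta_hat
  score <- function(rho) {
    n_cont <- continuous_cn(r, rho, psi_t)
    n_int <- pmax(0, round(n_cont))
    sum(seg_lengths * (n_cont - n_int)^2)
  }
  gof <- vapply(grid, score, numeric(1))
  k <- length(grid)
  is_lmin <- rep(FALSE, k)
  if (k >= 3) {
    for (i in 2:(k - 1)) is_lmin[i] <- gof[i] < gof[i - 1] && gof[i] < gof[i + 1]
  }
  if (any(is_lmin)) {
    cand <- which(is_lmin)
    best <- cand[gof[cand] <= min(gof[cand]) + 1e-12]
    i_hat <- max(best) ## ties toward higher purity
    rho_hat <- grid[i_hat]
  } else {
    rho_hat <- 1
  }
  n_cont <- continuous_cn(r, rho_hat, psi_t)
  n_int <- pmax(0L, as.integer(round(n_cont)))
  structure(list(rho_hat = rho_hat, gof = data.frame(rho = grid, gof = gof),
                 cn_cont = n_cont, cn_int = n_int,
                 local_minima = grid[is_lmin], delta_hat = delta_hat),
            class = "cn_fit")
}

#' @export
print.cn_fit <- function(x, ...) {
  cat(sprintf("low-pass CN fit: rho = %.2f, %d segments, gof = %.4g\n",
              x$rho_hat, length(x$cn_int),
              min(x$gof$gof[x$gof$rho == x$rho_hat])))
  invisible(x)
}

#' Fit purity and integer states for every sample of a segment set
#'
#' @param segment_set Result of [segment_joint()].
#' @param manifest Data frame sample, psi_t (integer tumour ploidy per
#'   sample).
#' @inheritParams fit_purity_cn
#' @return List: `fits` (data frame sample, rho_hat, gof_min), `states`
#'   (matrix segments x samples of integer states), `fit_objects`.
#' @export
fit_cna_all <- function(segment_set, manifest, rho_step = 0.01) {
  stopifnot(inherits(segment_set, "segment_set"),
            all(c("sample", "psi_t") %in% names(manifest)))
  lens <- segment_set$segments$n_bins
  states <- matrix(NA_integer_, nrow(segment_set$segments), nrow(manifest),
                   dimnames = list(rownames(segment_set$means), manifest$sample))
  fit_objects <- list()
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    s <- manifest$sample[i]
    fit <- fit_purity_cn(segment_set$means[, s], lens, manifest$psi_t[i],
                         rho_step = rho_step)
    states[, s] <<- fit$cn_int
    fit_objects[[s]] <<- fit
    data.frame(sample = s, rho_hat = fit$rho_hat, gof_min = min(fit$gof$gof),
               stringsAsFactors = FALSE)
  })
  list(fits = do.call(rbind, rows), states = states, fit_objects = fit_objects)
}
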