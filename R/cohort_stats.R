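## Cohort-level statistics: Fisher exact comparisons of driver mutation
## frequencies, microsatellite-instability classification, adenoma versus
## carcinoma SCAA burden with read subsampling, and SCAA heritability
## (within- versus between-region divergence, and the correlation of
## genetic with epigenetic distance).

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p-value defined as the sum of hypergeometric probabilities of
#' all tables with the given margins whose probability does not exceed that
#' of the observed table (the classic definition used for driver-frequency
#' comparisons between cohorts).
#'
#' @param a,b,c,d Non-negative integer cell counts: rows are
#'   mutated/not-mutated, columns the two cohorts.
#' @return The two-sided p-value.
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers")
  }
  stats::fisher.test(matrix(counts, nrow = 2))$p.value
}

#' Classify microsatellite status from the mutated-microsatellite fraction
#'
#' MSI when strictly more than `threshold` of assayed microsatellites are
#' mutated; MSS otherwise. A clinical override reproduces reclassification
#' of low-purity cases whose sequencing-based score is unreliable.
#'
#' @param fraction_mutated Fraction in `[0, 1]`.
#' @param threshold Critical value (default 0.30).
#' @param clinical_override `NA` (none), `"MSI"` or `"MSS"`.
#' @return `"MSI"` or `"MSS"`.
#' @export
msi_classify <- function(fraction_mutated, threshold = 0.30,
                         clinical_override = NA_character_) {
  stopifnot(fraction_mutated >= 0, fraction_mutated <= 1)
  if (!is.na(clinical_override)) {
    stopifnot(clinical_override %in% c("MSI", "MSS"))
    return(clinical_override)
  }
  if (fraction_mutated > threshold) "MSI" else "MSS"
}

#' Subsample a count vector without replacement
#'
#' Multivariate hypergeometric draw: `n_target` reads are drawn without
#' replacement from the pooled reads underlying `x`, preserving expected
#' per-category proportions. A no-op when `n_target >= sum(x)`.
#'
#' @param x Non-negative integer vector.
#' @param n_target Number of reads to keep.
#' @return Integer vector of the same length with sum `min(n_target, sum(x))`.
#' @export
subsample_counts <- function(x, n_target) {
  stopifnot(all(x >= 0), n_target >= 0)
  n_target <- floor(n_target)
  total <- sum(x)
  if (n_target >= total) return(as.integer(x))
  out <- integer(length(x))
  remaining <- total
  left <- n_target
  for (i in seq_along(x)) {
    if (left == 0L) break
    ## draw the category's share from the remaining pool
    k <- stats::rhyper(1, x[i], remaining - x[i], left)
    out[i] <- k
    left <- left - k
    remaining <- remaining - x[i]
  }
  out
}

#' Adenoma versus carcinoma SCAA burden with read subsampling
#'
#' Carcinoma lesions are subsampled (without replacement) to the median
#' adenoma read total so that burden differences cannot be driven by depth;
#' per lesion, peaks significantly above (gains) or below (losses) the
#' normal-pool expectation under the NB model are counted; gains and losses
#' are each compared between lesion types with a Welch two-sided t-test.
#'
#' @param counts Matrix peaks x lesions of insertion counts.
#' @param type Character per lesion: `"adenoma"` or `"carcinoma"`.
#' @param normal_counts Matrix peaks x normal-samples (reference pool).
#' @param dispersion NB dispersion for the significance cut.
#' @param alpha Per-peak two-tail level.
#' @param seed Seed for the subsampling.
#' @return List: `t_gain`, `p_gain`, `t_loss`, `p_loss`, `burden` (data
#'   frame lesion, type, reads_used, n_gain, n_loss, subsampled).
#' @export
burden_comparison <- function(counts, type, normal_counts, dispersion = 0.1,
                              alpha = 0.01, seed = 1L) {
  stopifnot(is.matrix(counts), ncol(counts) == length(type),
            all(type %in% c("adenoma", "carcinoma")),
            sum(type == "adenoma") >= 2, sum(type == "carcinoma") >= 2)
  target <- stats::median(colSums(counts[, type == "adenoma", drop = FALSE]))
  ref <- rowMeans(normal_counts)
  with_seed(stage_seed(seed, "burden"), {
    rows <- lapply(seq_len(ncol(counts)), function(j) {
      x <- counts[, j]
      subsampled <- FALSE
      if (type[j] == "carcinoma" && sum(x) > target) {
        x <- subsample_counts(x, target)
        subsampled <- TRUE
      }
      n <- sum(x)
      ## composition-robust scaling of the normal reference to this lesion
      ## (trimmed mean of M-values, so a few true SCAAs cannot shift the
      ## baseline)
      M <- log2((x + 0.5) / (ref + 0.5))
      keep <- M >= stats::quantile(M, 0.3) & M <= stats::quantile(M, 0.7)
      mu <- pmax(ref * 2^mean(M[keep]), 1e-8)
      size <- 1 / dispersion
      p_hi <- stats::pnbinom(x - 1, size = size, mu = mu, lower.tail = FALSE)
      p_lo <- stats::pnbinom(x, size = size, mu = mu)
      data.frame(lesion = colnames(counts)[j], type = type[j], reads_used = n,
                 n_gain = sum(p_hi <= alpha), n_loss = sum(p_lo <= alpha),
                 subsampled = subsampled, stringsAsFactors = FALSE)
    })
    burden <- do.call(rbind, rows)
    tg <- stats::t.test(n_gain ~ type, data = burden)
    tl <- stats::t.test(n_loss ~ type, data = burden)
    list(t_gain = unname(tg$statistic), p_gain = tg$p.value,
         t_loss = unname(tl$statistic), p_loss = tl$p.value,
         burden = burden)
  })
}

#' Heritability of SCAA profiles across tumour regions
#'
#' Tests whether samples from the same tumour region are epigenetically
#' closer than samples from different regions, controlling for differences
#' in TSS enrichment and total read count, and (optionally) whether
#' epigenetic distance follows genetic distance after controlling for
#' purity. The within/between test regresses pairwise Euclidean SCAA
#' distance on a same-region indicator plus covariate differences; because
#' pairwise distances are not independent, the p-value comes from permuting
#' region labels. The genetic-epigenetic association is a partial Mantel
#' correlation (via \code{vegan}).
#'
#' @param profiles Matrix samples x peaks of normalized accessibility
#'   signals.
#' @param region Region label per sample.
#' @param tsse,reads Per-sample covariates.
#' @param genetic_dist Optional samples x samples genetic distance matrix.
#' @param purity Optional per-sample purity (required with
#'   `genetic_dist`).
#' @param n_perm Number of permutations.
#' @param seed Seed.
#' @return List: `coefficient` (same-region effect on distance; negative
#'   means within < between), `p` (permutation p for within < between),
#'   `mantel_r`, `mantel_p` (NA when genetic data absent), `testable`.
#' @export
heritability_tests <- function(profiles, region, tsse, reads,
                               genetic_dist = NULL, purity = NULL,
                               n_perm = 999, seed = 1L) {
  stopifnot(is.matrix(profiles), nrow(profiles) == length(region))
  D <- as.matrix(stats::dist(profiles))
  if (max(D) < 1e-12) {
    return(list(coefficient = NA_real_, p = NA_real_, mantel_r = NA_real_,
                mantel_p = NA_real_, testable = FALSE))
  }
  n <- nrow(D)
  pair <- which(upper.tri(D), arr.ind = TRUE)
  d_epi <- D[pair]
  d_tsse <- abs(tsse[pair[, 1]] - tsse[pair[, 2]])
  d_reads <- abs(reads[pair[, 1]] - reads[pair[, 2]])
  same_stat <- function(reg) {
    same <- as.numeric(reg[pair[, 1]] == reg[pair[, 2]])
    stats::coef(stats::lm(d_epi ~ same + d_tsse + d_reads))["same"]
  }
  obs <- same_stat(region)
  perm <- with_seed(stage_seed(seed, "heritability"), {
    vapply(seq_len(n_perm), function(i) same_stat(sample(region)), numeric(1))
  })
  p <- (1 + sum(perm <= obs)) / (n_perm + 1) ## one-sided: within closer
  mantel_r <- NA_real_; mantel_p <- NA_real_
  if (!is.null(genetic_dist)) {
    stopifnot(!is.null(purity))
    d_pur <- as.matrix(stats::dist(purity))
    mt <- with_seed(stage_seed(seed, "mantel"), {
      vegan::mantel.partial(stats::as.dist(D), stats::as.dist(genetic_dist),
                            stats::as.dist(d_pur), permutations = n_perm)
    })
    mantel_r <- mt$statistic
    mantel_p <- mt$signif
  }
  list(coefficient = unname(obs), p = p, mantel_r = unname(mantel_r),
       mantel_p = mantel_p, testable = TRUE)
}
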