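## Somatic chromatin accessibility alteration (SCAA) detection.
##
## From fragment records to SCAA calls: Tn5 cut-site extraction, peak
## filtering and iterative merging, copy-number- and purity-aware
## overdispersed count testing of each patient's glands against a pool of
## normal samples, cross-patient recurrence, subclonality testing within a
## tumour, and association with gene expression.

#' Extract Tn5 cut sites from fragment records
#'
#' Each fragment yields two cut sites: the forward-read site shifted by -4
#' bases and the reverse-read site shifted by +5 bases. Fragments are
#' classified by insertion size into nucleosome-free (<= 100 bp) and
#' nucleosome-associated (180-620 bp) tracks; fragments of intermediate or
#' larger size belong to neither class and are dropped.
#'
#' @param fragments Data frame chrom, start, end (0-based half-open), and
#'   optionally sample.
#' @return Data frame chrom, pos, sample, insert_size, class
#'   (`"nucleosome_free"` or `"nucleosome"`); attribute `n_clipped` counts
#'   cut sites clipped at coordinate 0.
#' @export
shift_cut_sites <- function(fragments) {
  stopifnot(all(c("chrom", "start", "end") %in% names(fragments)))
  if (nrow(fragments) == 0) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      sample = character(0), insert_size = integer(0),
                      class = character(0), stringsAsFactors = FALSE)
    attr(out, "n_clipped") <- 0L
    return(out)
  }
  size <- fragments$end - fragments$start
  class <- rep(NA_character_, length(size))
  class[size <= 100] <- "nucleosome_free"
  class[size >= 180 & size <= 620] <- "nucleosome"
  keep <- !is.na(class)
  fr <- fragments[keep, , drop = FALSE]
  size <- size[keep]; class <- class[keep]
  smp <- if ("sample" %in% names(fr)) fr$sample else rep(NA_character_, nrow(fr))
  fwd <- fr$start - 4L
  rev <- fr$end + 5L
  n_clipped <- sum(fwd < 0L)
  if (n_clipped > 0) {
    warning(sprintf("%d cut sites clipped at coordinate 0", n_clipped))
    fwd <- pmax(0L, fwd)
  }
  out <- data.frame(chrom = rep(fr$chrom, 2L),
                    pos = c(fwd, rev),
                    sample = rep(smp, 2L),
                    insert_size = rep(as.integer(size), 2L),
                    class = rep(class, 2L), stringsAsFactors = FALSE)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Filter per-region peak calls and merge them iteratively
#'
#' Each region's call list is filtered to q-value < `q_max`, enrichment >
#' `enrichment_min`, and at most the `top_n` most significant peaks. All
#' surviving calls are then merged iteratively: the most significant call
#' becomes the representative of every call overlapping it, and the group is
#' removed; this repeats until no calls remain, so the final intervals are
#' non-overlapping. A merged peak is retained when it was supported by more
#' than `min_tumour_regions` tumour-region call sets or by the panel of
#' normals.
#'
#' @param calls Named list of data frames (chrom, start, end, q_value,
#'   enrichment), one per region call set.
#' @param normal_names Names of elements that constitute the normal panel.
#' @param q_max,enrichment_min,top_n Per-region filter thresholds.
#' @param min_tumour_regions Retention requires support in strictly more
#'   than this many tumour regions (default 2, i.e. > 2 regions).
#' @return Data frame chrom, start, end, q_value, enrichment,
#'   support_tumour, support_normal, retained.
#' @export
filter_and_merge_peaks <- function(calls, normal_names = "normal_panel",
                                   q_max = 0.001, enrichment_min = 4,
                                   top_n = 20000, min_tumour_regions = 2) {
  stopifnot(is.list(calls), !is.null(names(calls)))
  filtered <- lapply(names(calls), function(nm) {
    df <- calls[[nm]]
    df <- df[df$q_value < q_max & df$enrichment > enrichment_min, , drop = FALSE]
    if (nrow(df) > top_n) df <- df[order(df$q_value)[seq_len(top_n)], , drop = FALSE]
    if (nrow(df)) df$source <- nm
    df
  })
  all <- do.call(rbind, filtered[vapply(filtered, nrow, integer(1)) > 0])
  if (is.null(all) || nrow(all) == 0) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      q_value = numeric(0), enrichment = numeric(0),
                      support_tumour = integer(0), support_normal = logical(0),
                      retained = logical(0)))
  }
  all <- all[order(all$q_value), ]
  rownames(all) <- NULL
  alive <- rep(TRUE, nrow(all))
  out <- list()
  while (any(alive)) {
    i <- which(alive)[1L] ## most significant remaining call
    ov <- alive & all$chrom == all$chrom[i] &
      all$start < all$end[i] & all$end > all$start[i]
    src <- unique(all$source[ov])
    out[[length(out) + 1L]] <- data.frame(
      chrom = all$chrom[i], start = all$start[i], end = all$end[i],
      q_value = all$q_value[i], enrichment = all$enrichment[i],
      support_tumour = length(setdiff(src, normal_names)),
      support_normal = any(src %in% normal_names), stringsAsFactors = FALSE)
    alive[ov] <- FALSE
  }
  res <- do.call(rbind, out)
  res$retained <- res$support_tumour > min_tumour_regions | res$support_normal
  res[order(res$chrom, res$start), ]
}

#' Copy-number adjustment factor for the expected ATAC signal
#'
#' The accessibility signal expected at a locus of copy number `pi_loc` in a
#' sample of purity `rho` from a tumour of ploidy `psi`, relative to the
#' normal signal, is `(2(1-rho) + pi_loc*rho) / (2(1-rho) + psi*rho)`. The
#' factor enters the count model as a multiplicative offset.
#'
#' @param rho Purity.
#' @param pi_loc Locus copy number.
#' @param psi Tumour ploidy.
#' @return Multiplicative factor (1 when `rho = 0` or `pi_loc = psi`).
#' @export
cn_adjust_factor <- function(rho, pi_loc, psi) {
  denom <- 2 * (1 - rho) + psi * rho
  if (any(denom <= 0)) stop("degenerate adjustment: zero expected normal signal")
  (2 * (1 - rho) + pi_loc * rho) / denom
}

#' Read-count-weighted pooled copy-number adjustment factor
#'
#' For a pool of samples, the factor is the average of the per-sample
#' factors weighted by each sample's total read count.
#'
#' @inheritParams cn_adjust_factor
#' @param reads Total reads per sample.
#' @export
pooled_cn_adjust_factor <- function(rho, pi_loc, psi, reads) {
  stats::weighted.mean(cn_adjust_factor(rho, pi_loc, psi), reads)
}

#' TMM-style size factors for a count matrix
#'
#' Trimmed-mean-of-M-values scaling against a reference sample (the one
#' whose upper quartile is closest to the mean upper quartile), with a
#' pseudo-count of 0.5 for zero handling, 30% trim on M and 5% trim on A.
#' Factors are normalized to geometric mean 1 and absorb sequencing depth:
#' they multiply directly into the count-model offset.
#'
#' @param counts Matrix features x samples with at least one positive entry
#'   per sample.
#' @param logratio_trim,abs_trim Trim fractions for M and A values.
#' @return Named numeric vector of per-sample factors.
#' @export
size_factors <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  stopifnot(is.matrix(counts))
  zero <- colSums(counts) == 0
  if (any(zero)) {
    stop(sprintf("all-zero sample(s): %s",
                 paste(colnames(counts)[zero], collapse = ", ")))
  }
  uq <- apply(counts, 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  xr <- counts[, ref]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    use <- x > 0 | xr > 0
    M <- log2(x[use] + 0.5) - log2(xr[use] + 0.5)
    A <- 0.5 * (log2(x[use] + 0.5) + log2(xr[use] + 0.5))
    keepM <- M >= stats::quantile(M, logratio_trim) &
      M <= stats::quantile(M, 1 - logratio_trim)
    keepA <- A >= stats::quantile(A, abs_trim) &
      A <= stats::quantile(A, 1 - abs_trim)
    2^mean(M[keepM & keepA])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' Global negative-binomial dispersion across peaks
#'
#' Cox-Reid adjusted profile-likelihood estimate of a single dispersion
#' shared by all peaks: per-peak, per-group means are estimated from
#' offset-normalized counts and profiled out; the adjustment term (half the
#' log determinant of the mean-parameter information) removes the downward
#' bias that plain plug-in profiling incurs from fitting one mean per
#' group per peak.
#'
#' @param counts Matrix peaks x samples.
#' @param log_offsets Matrix of log offsets (same shape), e.g.
#'   `log(size_factor * cn_factor)`.
#' @param groups Factor of length ncol assigning samples to groups.
#' @return Estimated dispersion (1 / size).
#' @export
estimate_global_dispersion <- function(counts, log_offsets, groups) {
  stopifnot(dim(counts)[2] == length(groups))
  groups <- as.factor(groups)
  e <- exp(log_offsets)
  mu <- matrix(0, nrow(counts), ncol(counts))
  for (g in levels(groups)) {
    j <- groups == g
    mg <- rowSums(counts[, j, drop = FALSE]) / rowSums(e[, j, drop = FALSE])
    mu[, j] <- mg * e[, j]
  }
  mu <- pmax(mu, 1e-8)
  gidx <- lapply(levels(groups), function(g) which(groups == g))
  apl_nll <- function(log_disp) {
    phi <- exp(log_disp)
    ll <- sum(stats::dnbinom(counts, size = 1 / phi, mu = mu, log = TRUE))
    ## Cox-Reid: working weights w = mu / (1 + phi * mu); the information of
    ## a group's log-mean is the within-group weight sum
    w <- mu / (1 + phi * mu)
    cr <- 0
    for (j in gidx) {
      cr <- cr + sum(log(rowSums(w[, j, drop = FALSE])))
    }
    -(ll - 0.5 * cr)
  }
  opt <- stats::optimize(apl_nll, interval = log(c(1e-4, 5)))
  exp(opt$minimum)
}

#' Overdispersed count test of one peak: patient glands versus normal pool
#'
#' Negative-binomial generalized linear model (log link, fixed dispersion)
#' of insertion counts on a tumour/normal indicator, with
#' `log(size factor * copy-number factor)` as offset; the p-value comes from
#' the likelihood-ratio test against the intercept-only model.
#'
#' @param tumour_counts,normal_counts Integer count vectors.
#' @param tumour_offsets,normal_offsets Log offsets per sample (size factor
#'   times copy-number adjustment).
#' @param dispersion NB dispersion (1 / size).
#' @return List with `lfc` (log2 fold change tumour vs normal), `p`, and
#'   `direction` (`"gain"`/`"loss"`); all `NA` on non-convergence.
#' @export
test_scaa <- function(tumour_counts, normal_counts, tumour_offsets,
                      normal_offsets, dispersion) {
  stopifnot(dispersion > 0, length(tumour_counts) >= 2)
  y <- c(normal_counts, tumour_counts)
  grp <- rep(c(0L, 1L), c(length(normal_counts), length(tumour_counts)))
  off <- c(normal_offsets, tumour_offsets)
  fam <- MASS::negative.binomial(theta = 1 / dispersion)
  res <- tryCatch({
    fit1 <- stats::glm(y ~ grp + offset(off), family = fam)
    fit0 <- stats::glm(y ~ 1 + offset(off), family = fam)
    if (!fit1$converged || !fit0$converged) stop("no convergence")
    lrt <- fit0$deviance - fit1$deviance
    p <- stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
    lfc <- unname(stats::coef(fit1)["grp"]) / log(2)
    list(lfc = lfc, p = p, direction = if (lfc > 0) "gain" else "loss")
  }, error = function(e) list(lfc = NA_real_, p = NA_real_, direction = NA_character_))
  res
}

#' Call SCAAs for every (patient, peak) pair against the normal pool
#'
#' Applies [test_scaa()] peak by peak and patient by patient, restricting
#' each patient's set to glands above the purity threshold.
#'
#' @param counts Matrix peaks x samples.
#' @param samples Data frame with sample, patient, region, purity.
#' @param log_offsets Matrix of log offsets (size factor x CN adjustment).
#' @param dispersion Global NB dispersion.
#' @param purity_min Only tumour glands with purity above this enter
#'   (normal-region samples form the pool regardless).
#' @param normal_region Region label of normal samples.
#' @return Data frame patient, peak_id, lfc, p, direction.
#' @export
call_scaas <- function(counts, samples, log_offsets, dispersion,
                       purity_min = 0.4, normal_region = "E") {
  norm_idx <- which(samples$region == normal_region)
  stopifnot(length(norm_idx) >= 2)
  out <- list()
  for (p in unique(samples$patient)) {
    tum_idx <- which(samples$patient == p & samples$region != normal_region &
                       samples$purity > purity_min)
    if (length(tum_idx) < 2) next
    for (i in seq_len(nrow(counts))) {
      r <- test_scaa(counts[i, tum_idx], counts[i, norm_idx],
                     log_offsets[i, tum_idx], log_offsets[i, norm_idx],
                     dispersion)
      out[[length(out) + 1L]] <- data.frame(
        patient = p, peak_id = rownames(counts)[i], lfc = r$lfc, p = r$p,
        direction = if (is.null(r$direction)) NA_character_ else r$direction,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-patient recurrence of SCAAs
#'
#' A peak is recurrently altered when it is significant (p <= `alpha`) with
#' the same direction in at least `ceiling(min_frac * n_cases)` cases.
#'
#' @param results Data frame patient, peak_id, p, direction (from
#'   [call_scaas()]).
#' @param n_cases Number of cases tested (denominator of the recurrence
#'   fraction).
#' @param alpha Per-patient significance level.
#' @param min_frac Minimum fraction of cases.
#' @return Data frame peak_id, direction, n_significant, recurrent.
#' @export
recurrence <- function(results, n_cases, alpha = 0.01, min_frac = 0.2) {
  need <- ceiling(min_frac * n_cases)
  sig <- results[!is.na(results$p) & results$p <= alpha, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(data.frame(peak_id = character(0), direction = character(0),
                      n_significant = integer(0), recurrent = logical(0)))
  }
  tab <- stats::aggregate(list(n_significant = sig$patient),
                          by = list(peak_id = sig$peak_id, direction = sig$direction),
                          FUN = function(x) length(unique(x)))
  tab$recurrent <- tab$n_significant >= need
  tab[order(-tab$n_significant), ]
}

#' Subclonality test for one peak within one tumour
#'
#' Likelihood-ratio test between a full NB model `counts ~ purity + region`
#' and a reduced model `counts ~ purity`, both with the size-factor /
#' copy-number offset; samples from the same region act as biological
#' replicates. Requires at least two regions with at least two samples each,
#' otherwise the event is untestable.
#'
#' @param counts Counts of the peak in the patient's tumour glands.
#' @param purity,region Per-gland covariates.
#' @param log_offsets Per-gland log offsets.
#' @param dispersion Global NB dispersion.
#' @return List `p` (LRT p-value, NA if untestable), `region_lfc` (named
#'   per-region log2 deviations), `testable`.
#' @export
test_subclonality <- function(counts, purity, region, log_offsets, dispersion) {
  region <- droplevels(as.factor(region))
  reps <- table(region)
  if (length(reps) < 2 || any(reps < 2)) {
    return(list(p = NA_real_, region_lfc = NULL, testable = FALSE))
  }
  fam <- MASS::negative.binomial(theta = 1 / dispersion)
  res <- tryCatch({
    full <- stats::glm(counts ~ purity + region + offset(log_offsets), family = fam)
    red <- stats::glm(counts ~ purity + offset(log_offsets), family = fam)
    lrt <- max(red$deviance - full$deviance, 0)
    p <- stats::pchisq(lrt, df = length(levels(region)) - 1, lower.tail = FALSE)
    cf <- stats::coef(full)
    rterm <- grep("^region", names(cf), value = TRUE)
    lfc <- c(0, cf[rterm]) / log(2)
    names(lfc) <- levels(region)
    list(p = p, region_lfc = lfc, testable = TRUE)
  }, error = function(e) list(p = NA_real_, region_lfc = NULL, testable = FALSE))
  res
}

#' Subclonality verdicts across a set of recurrent SCAA events
#'
#' Applies [test_subclonality()] per event, adjusts p-values by
#' Benjamini-Hochberg across tested events, and classifies an event as
#' subclonal only when (i) adjusted p < `alpha`, (ii) the region-level
#' direction agrees with the bulk-level call, and (iii) for gains, a called
#' peak exists within `gain_window` bp of the event.
#'
#' @param events List of per-event lists with elements `counts`, `purity`,
#'   `region`, `log_offsets`, `direction` (bulk call, "gain"/"loss"),
#'   `position` (event centre) and `chrom`.
#' @param dispersion Global NB dispersion.
#' @param called_peaks Data frame chrom, start, end of called peaks (for the
#'   gain filter); NULL skips the filter.
#' @param alpha FDR level.
#' @param gain_window Maximum distance to a called peak for gains (bp).
#' @return Data frame event, p, p_adj, verdict (subclonal / clonal /
#'   untestable), region_pattern.
#' @export
call_subclonality <- function(events, dispersion, called_peaks = NULL,
                              alpha = 0.05, gain_window = 500) {
  fits <- lapply(events, function(ev) {
    test_subclonality(ev$counts, ev$purity, ev$region, ev$log_offsets, dispersion)
  })
  p <- vapply(fits, function(f) f$p, numeric(1))
  testable <- vapply(fits, function(f) f$testable, logical(1)) & !is.na(p)
  p_adj <- rep(NA_real_, length(p))
  p_adj[testable] <- stats::p.adjust(p[testable], method = "BH")
  verdict <- rep("untestable", length(events))
  pattern <- rep(NA_character_, length(events))
  for (i in seq_along(events)) {
    if (!testable[i]) next
    ev <- events[[i]]
    f <- fits[[i]]
    dev <- f$region_lfc - mean(f$region_lfc)
    aff <- names(dev)[if (ev$direction == "gain") dev > 0 else dev < 0]
    pattern[i] <- paste(sort(aff), collapse = ",")
    is_sub <- p_adj[i] < alpha
    if (is_sub && !is.null(called_peaks) && identical(ev$direction, "gain")) {
      near <- called_peaks$chrom == ev$chrom &
        abs((called_peaks$start + called_peaks$end) / 2 - ev$position) <= gain_window
      if (!any(near)) is_sub <- FALSE
    }
    ## direction sanity: the extreme region must deviate in the called direction
    if (is_sub) {
      ok_dir <- if (ev$direction == "gain") max(dev) > 0 else min(dev) < 0
      if (!ok_dir) is_sub <- FALSE
    }
    verdict[i] <- if (is_sub) "subclonal" else "clonal"
  }
  data.frame(event = seq_along(events), p = p, p_adj = p_adj,
             verdict = verdict, region_pattern = pattern,
             stringsAsFactors = FALSE)
}

#' Association of recurrent SCAAs with gene expression
#'
#' For each peak-associated gene, expression counts are contrasted between
#' patients with the accessibility alteration and those without, with all
#' normal samples as their own level, using an NB model with a library-size
#' offset. Promoter events use a one-sided test in the direction of the
#' accessibility change; enhancer events a two-sided test. P-values are
#' BH-adjusted across genes.
#'
#' @param expr Matrix genes x samples of expression counts.
#' @param sample_group Factor per sample: `"altered"`, `"non_altered"`, or
#'   `"normal"`.
#' @param directions Named character vector per gene: `"gain"`, `"loss"`
#'   (one-sided, promoters) or `"two_sided"` (enhancers).
#' @param dispersion NB dispersion for the expression counts.
#' @param log_offsets Per-sample log library-size offsets (default log of
#'   column sums).
#' @return Data frame gene, lfc, stat, p, fdr.
#' @export
expression_association <- function(expr, sample_group, directions,
                                   dispersion = 0.1, log_offsets = NULL) {
  stopifnot(is.matrix(expr), ncol(expr) == length(sample_group))
  sample_group <- factor(sample_group, levels = c("normal", "non_altered", "altered"))
  if (is.null(log_offsets)) log_offsets <- log(colSums(expr))
  fam <- MASS::negative.binomial(theta = 1 / dispersion)
  rows <- lapply(rownames(expr), function(g) {
    dir <- directions[[g]]
    if (is.null(dir) || is.na(dir)) return(NULL) ## no annotated gene: no test
    y <- expr[g, ]
    fit <- tryCatch(stats::glm(y ~ sample_group + offset(log_offsets), family = fam),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      return(data.frame(gene = g, lfc = NA_real_, stat = NA_real_, p = NA_real_))
    }
    cf <- summary(fit)$coefficients
    b <- cf["sample_groupaltered", 1] - cf["sample_groupnon_altered", 1]
    se <- sqrt(stats::vcov(fit)["sample_groupaltered", "sample_groupaltered"] +
                 stats::vcov(fit)["sample_groupnon_altered", "sample_groupnon_altered"] -
                 2 * stats::vcov(fit)["sample_groupaltered", "sample_groupnon_altered"])
    z <- b / se
    p <- switch(dir,
                gain = stats::pnorm(z, lower.tail = FALSE),
                loss = stats::pnorm(z, lower.tail = TRUE),
                two_sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
    data.frame(gene = g, lfc = b / log(2), stat = z, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(res)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}

#' Filter an expression matrix to expressed, purity-robust genes
#'
#' Two-stage filter: (1) keep genes with at least `min_tpm` transcripts per
#' million in at least `min_frac` of tumour samples; (2) drop genes whose
#' expression decreases significantly with purity (per-gene linear model
#' with patient as a fixed covariate; negative purity coefficient at
#' BH-adjusted p < `alpha`), which removes signal dominated by contaminating
#' normal cells.
#'
#' @param tpm Matrix genes x samples of TPM values.
#' @param purity Purity per sample.
#' @param patient Patient label per sample.
#' @param is_tumour Logical per sample (default: purity > 0).
#' @param min_tpm,min_frac Stage-1 thresholds.
#' @param alpha Stage-2 FDR level.
#' @return Character vector of retained gene names.
#' @export
filter_expressed_genes <- function(tpm, purity, patient, is_tumour = purity > 0,
                                   min_tpm = 10, min_frac = 0.05, alpha = 0.05) {
  stopifnot(is.matrix(tpm), ncol(tpm) == length(purity))
  frac <- rowMeans(tpm[, is_tumour, drop = FALSE] >= min_tpm)
  genes <- rownames(tpm)[frac >= min_frac]
  if (length(genes) == 0) return(character(0))
  pat <- as.factor(patient[is_tumour])
  rho <- purity[is_tumour]
  multi_pat <- nlevels(droplevels(pat)) > 1
  stats_tab <- t(vapply(genes, function(g) {
    y <- log2(tpm[g, is_tumour] + 1)
    fit <- if (multi_pat) stats::lm(y ~ rho + pat) else stats::lm(y ~ rho)
    cf <- summary(fit)$coefficients
    if (!"rho" %in% rownames(cf)) return(c(0, 1))
    cf["rho", c(1, 4)]
  }, numeric(2)))
  padj <- stats::p.adjust(stats_tab[, 2], method = "BH")
  drop <- stats_tab[, 1] < 0 & padj < alpha
  genes[!drop]
}
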