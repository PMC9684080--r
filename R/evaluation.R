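## End-to-end evaluation harnesses. Each function simulates a cohort under
## the study conditions encoded in the generator defaults, runs the
## corresponding analysis stage, and scores recovery against the generator's
## ground truth. They power both the package's acceptance tests and the
## reproduction script.

#' Fisher exact tests of adenoma driver-mutation frequencies
#'
#' The three published cohort comparisons of adenoma mutation frequencies
#' (TP53 2/8 vs 4/135; KRAS 2/8 vs 13/135; APC 4/8 vs 73/135).
#'
#' @return Named vector of two-sided p-values.
#' @export
eval_fisher_examples <- function() {
  c(tp53 = fisher_exact_two_sided(2, 6, 4, 131),
    kras = fisher_exact_two_sided(2, 6, 13, 122),
    apc = fisher_exact_two_sided(4, 4, 73, 62))
}

#' Purity recovery from simulated ATAC allele counts
#'
#' Simulates glands spanning a purity grid, with clonal SNVs at the given
#' depth, and scores the maximum-likelihood estimates against truth.
#'
#' @param purities True purities assigned to the tumour glands.
#' @param n_sites Clonal SNV sites per patient.
#' @param depth Mean reads per site.
#' @param seed Seed.
#' @return List: `mean_abs_error`, `max_abs_error`, `per_gland` data frame.
#' @export
eval_purity_recovery <- function(purities = seq(0.2, 0.9, length.out = 20),
                                 n_sites = 500, depth = 30, seed = 1L) {
  cfg <- cohort_config(n_patients = 1, regions_per_tumour = 4,
                       glands_per_region = ceiling(length(purities) / 4),
                       purity_values = purities, sequencing_depth = depth,
                       peak_count = 10, seed = seed)
  co <- simulate_cohort(cfg)
  al <- simulate_allele_counts(co, n_sites = n_sites, depth = depth)
  tum <- co$samples$sample[co$samples$region != "E"][seq_along(purities)]
  est <- estimate_purity_all(al[al$sample %in% tum, ])
  est$truth <- co$truth$purity[est$sample]
  err <- abs(est$rho_hat - est$truth)
  list(mean_abs_error = mean(err), max_abs_error = max(err), per_gland = est)
}

#' Integer copy-number and purity recovery from simulated low-pass bins
#'
#' @param n_patients Number of simulated patients.
#' @param samples_per_patient Tumour samples fitted per patient (segmented
#'   jointly); the emulated study profiled a median of eight low-pass
#'   samples per patient, so three is a conservative stand-in.
#' @param noise_sd Bin noise.
#' @param penalty Joint-segmentation penalty.
#' @param seed Seed.
#' @return List: `segment_accuracy`, `mean_rho_error`, `median_rho_error`,
#'   `n_segments`, `per_sample`.
#' @export
eval_cn_recovery <- function(n_patients = 50, samples_per_patient = 3,
                             noise_sd = 0.05, penalty = 0.2, seed = 1L) {
  ok <- 0L; all_seg <- 0L; errs <- c()
  for (i in seq_len(n_patients)) {
    co <- simulate_cohort(cohort_config(n_patients = 1, glands_per_region = 2,
                                        peak_count = 10,
                                        seed = stage_seed(seed, i)))
    smps <- co$samples$sample[co$samples$region != "E"][seq_len(samples_per_patient)]
    lp <- simulate_lowpass_bins(co, noise_sd = noise_sd, samples = smps)
    seg <- segment_joint(lp$bins, penalty = penalty)
    truth_state <- segment_state_at(
      co$truth$segments, "P01", seg$segments$contig,
      as.integer((seg$segments$start + seg$segments$end) / 2))
    for (sm in smps) {
      fit <- fit_purity_cn(seg$means[, sm], seg$segments$n_bins,
                           co$truth$ploidy[["P01"]])
      errs <- c(errs, abs(fit$rho_hat -
                            co$samples$purity[co$samples$sample == sm]))
      ok <- ok + sum(fit$cn_int == truth_state)
      all_seg <- all_seg + length(truth_state)
    }
  }
  list(segment_accuracy = ok / all_seg, mean_rho_error = mean(errs),
       median_rho_error = stats::median(errs), n_segments = all_seg,
       per_sample = errs)
}

#' Type-I error of the SCAA test on null peaks from the generator
#'
#' Simulates a cohort with no planted alterations, estimates size factors
#' and the global dispersion from the data, adjusts for the (real)
#' copy-number landscape, and measures the fraction of null peaks called at
#' `alpha` for one patient's glands versus the normal pool.
#'
#' @param n_peaks Number of null peaks.
#' @param n_glands Tumour glands used.
#' @param alpha Significance level.
#' @param seed Seed.
#' @return List: `type1`, `alpha`, `dispersion_hat`, `n_peaks`.
#' @export
eval_scaa_calibration <- function(n_peaks = 2000, n_glands = 8, alpha = 0.01,
                                  seed = 1L) {
  cfg <- cohort_config(n_patients = 2, glands_per_region = 3,
                       peak_count = n_peaks, scaa_fraction = 0,
                       purity_range = c(0.5, 0.95), seed = seed)
  co <- simulate_cohort(cfg)
  pt <- simulate_peak_counts(co)
  offs <- cn_offset_matrix(co, pt)
  disp <- estimate_global_dispersion(pt$counts, offs,
                                     paste(co$samples$patient,
                                           co$samples$region == "E"))
  tum <- co$samples$sample[co$samples$patient == "P01" &
                             co$samples$region != "E" &
                             co$samples$purity > 0.4][seq_len(n_glands)]
  nrm <- co$samples$sample[co$samples$region == "E"]
  ps <- vapply(seq_len(n_peaks), function(i) {
    test_scaa(pt$counts[i, tum], pt$counts[i, nrm],
              offs[i, tum], offs[i, nrm], disp)$p
  }, numeric(1))
  list(type1 = mean(ps <= alpha, na.rm = TRUE), alpha = alpha,
       dispersion_hat = disp, n_peaks = n_peaks)
}

#' Log-offset matrix combining size factors and copy-number adjustment
#'
#' Builds the per-(peak, sample) copy-number adjustment factors from the
#' cohort's copy-number landscape and combines them with per-sample size
#' factors into the log-offset matrix of the count model. When `sf` is not
#' supplied, size factors are estimated by [size_factors()] on the
#' CN-adjusted counts (counts divided by the adjustment factor), so that
#' they capture sequencing depth only and the copy-number effect is not
#' absorbed twice.
#'
#' @param cohort A `gland_cohort`.
#' @param peak_table A `peak_table`.
#' @param sf Optional per-sample size factors.
#' @return Matrix peaks x samples of log offsets.
#' @export
cn_offset_matrix <- function(cohort, peak_table, sf = NULL) {
  counts <- peak_table$counts
  cnf <- matrix(1, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  mid <- as.integer((peak_table$peaks$start + peak_table$peaks$end) / 2)
  for (j in seq_len(nrow(cohort$samples))) {
    smp <- cohort$samples[j, ]
    pi_loc <- segment_state_at(cohort$truth$segments, smp$patient,
                               peak_table$peaks$chrom, mid)
    cnf[, smp$sample] <- cn_adjust_factor(smp$purity, pi_loc,
                                          cohort$truth$ploidy[[smp$patient]])
  }
  if (is.null(sf)) sf <- size_factors(counts / cnf)
  log(sweep(cnf, 2, unlist(sf[colnames(cnf)]), `*`))
}

#' Power of the SCAA test for a planted gain
#'
#' Replicates of a single peak with a multiplicative gain in the tumour
#' glands, drawn from the generator's count model at diploid copy number.
#'
#' @param n_rep Replicates.
#' @param effect Planted fold change.
#' @param n_glands Tumour glands.
#' @param n_normals Normal-pool samples.
#' @param dispersion NB dispersion of the simulated counts (also supplied to
#'   the test).
#' @param alpha Significance level.
#' @param seed Seed.
#' @return List: `power`, `n_rep`.
#' @export
eval_scaa_power <- function(n_rep = 200, effect = 3, n_glands = 8,
                            n_normals = 6, dispersion = 0.05, alpha = 0.01,
                            seed = 1L) {
  hits <- with_seed(stage_seed(seed, "power"), {
    vapply(seq_len(n_rep), function(i) {
      mu <- stats::rlnorm(1, log(60), 0.6)
      sfT <- stats::rlnorm(n_glands, 0, 0.25)
      sfN <- stats::rlnorm(n_normals, 0, 0.25)
      yN <- stats::rnbinom(n_normals, size = 1 / dispersion, mu = mu * sfN)
      yT <- stats::rnbinom(n_glands, size = 1 / dispersion,
                           mu = effect * mu * sfT)
      r <- test_scaa(yT, yN, log(sfT), log(sfN), dispersion)
      !is.na(r$p) && r$p <= alpha && r$direction == "gain"
    }, logical(1))
  })
  list(power = mean(hits), n_rep = n_rep)
}

#' Specificity and sensitivity of the subclonality classification
#'
#' Two cohorts are simulated: one in which every planted SCAA is clonal
#' (all tumour regions) and one in which every planted SCAA is confined to
#' half of the regions. Each (altered peak, affected patient) pair is one
#' classification event.
#'
#' @param n_cohorts Cohorts simulated per arm.
#' @param seed Seed.
#' @return List: `specificity`, `sensitivity`, `n_clonal`, `n_subclonal`.
#' @export
eval_subclonality <- function(n_cohorts = 2, seed = 1L) {
  run_arm <- function(subfrac, seed) {
    verdicts <- character(0)
    for (cix in seq_len(n_cohorts)) {
      cfg <- cohort_config(n_patients = 3, glands_per_region = 3,
                           peak_count = 150, scaa_fraction = 0.2,
                           subclonal_fraction = subfrac,
                           purity_range = c(0.5, 0.95),
                           seed = stage_seed(seed, cix))
      co <- simulate_cohort(cfg)
      pt <- simulate_peak_counts(co)
      offs <- cn_offset_matrix(co, pt)
      tr <- pt$truth
      events <- list()
      for (i in which(tr$status != "unchanged")) {
        for (p in strsplit(tr$affected_patients[i], ",")[[1]]) {
          sel <- co$samples$patient == p & co$samples$region != "E" &
            co$samples$purity > 0.4
          if (sum(sel) < 4) next
          events[[length(events) + 1L]] <- list(
            counts = pt$counts[i, co$samples$sample[sel]],
            purity = co$samples$purity[sel],
            region = co$samples$region[sel],
            log_offsets = offs[i, co$samples$sample[sel]],
            direction = if (tr$status[i] == "gained") "gain" else "loss",
            position = (pt$peaks$start[i] + pt$peaks$end[i]) / 2,
            chrom = pt$peaks$chrom[i])
        }
      }
      v <- call_subclonality(events, cfg$nb_dispersion)
      verdicts <- c(verdicts, v$verdict[v$verdict != "untestable"])
    }
    verdicts
  }
  clonal <- run_arm(0, stage_seed(seed, "clonal"))
  subclonal <- run_arm(1, stage_seed(seed, "subclonal"))
  list(specificity = mean(clonal == "clonal"),
       sensitivity = mean(subclonal == "subclonal"),
       n_clonal = length(clonal), n_subclonal = length(subclonal))
}

#' Linearity of the TF footprint signal in purity
#'
#' One tumour region whose glands span five purity levels, plus normals;
#' the differential signal of the planted-gain TF is regressed on purity.
#' Also reports how far normal-versus-pool signals sit from zero across
#' TFs, in standard errors.
#'
#' @param purity_levels Purity levels of the five tumour glands.
#' @param n_tf TFs simulated (first quarter planted gains).
#' @param sites_per_tf Binding sites per TF.
#' @param seed Seed.
#' @return List: `r_squared` (planted TF), `slope`, `normal_center_z`
#'   (|mean| / SE of normal-vs-pool signals across TFs and normal glands),
#'   `signals`.
#' @export
eval_footprint <- function(purity_levels = c(0.2, 0.4, 0.6, 0.8, 1.0),
                           n_tf = 4, sites_per_tf = 400, seed = 1L) {
  cfg <- cohort_config(n_patients = 1, glands_per_region = length(purity_levels),
                       purity_values = purity_levels, peak_count = 10,
                       seed = seed)
  co <- simulate_cohort(cfg)
  keep <- co$samples$region %in% c("A", "E")
  co$samples <- co$samples[keep, ]
  tf <- simulate_tf_sites(co, n_tf = n_tf, sites_per_tf = sites_per_tf)
  fr <- simulate_fragments(co, tf, open_per_site = 5, background_frags = 20000)
  norm_s <- co$samples$sample[co$samples$region == "E"]
  tum_s <- co$samples$sample[co$samples$region == "A"]
  reads <- stats::setNames(co$samples$total_reads, co$samples$sample)
  gain_tf <- names(tf$truth)[tf$truth > 1][1]
  r2 <- NA_real_; slope <- NA_real_; sig_gain <- NULL
  norm_sigs <- c()
  for (tfn in unique(tf$sites$tf)) {
    st <- tf$sites[tf$sites$tf == tfn, ]
    mats <- lapply(co$samples$sample, function(s) {
      build_insertion_matrix(fr[fr$sample == s, ], st)
    })
    names(mats) <- co$samples$sample
    pool <- pool_insertion_matrices(mats[norm_s], reads[norm_s])
    norm_sigs <- c(norm_sigs, vapply(norm_s, function(s) {
      differential_signal(mats[[s]], pool)
    }, numeric(1)))
    if (tfn == gain_tf) {
      sig_gain <- vapply(tum_s, function(s) {
        differential_signal(mats[[s]], pool)
      }, numeric(1))
      rho <- co$samples$purity[match(tum_s, co$samples$sample)]
      fit <- stats::lm(sig_gain ~ rho)
      r2 <- summary(fit)$r.squared
      slope <- stats::coef(fit)[["rho"]]
    }
  }
  z <- abs(mean(norm_sigs)) / (stats::sd(norm_sigs) / sqrt(length(norm_sigs)))
  list(r_squared = r2, slope = slope, normal_center_z = z,
       signals = sig_gain)
}

#' Exposure recovery and trinucleotide-normalization round trip
#'
#' @param n_mut Catalogue size.
#' @param mix Two-signature mixture fitted at lambda = 0.
#' @param seed Seed.
#' @return List: `max_exposure_error`, `roundtrip_cosine`.
#' @export
eval_exposures <- function(n_mut = 1e5, mix = c(0.7, 0.3), seed = 1L) {
  S <- synthetic_signatures(6)
  e0 <- c(mix, rep(0, 4))
  x <- simulate_mutation_catalogue(S, e0, n_mut, seed = stage_seed(seed, "mix"))
  f <- fit_exposures(x, S, lambda = 0)
  err <- max(abs(f$exposures - e0))
  gc <- synthetic_trinucleotide_content()
  rc <- synthetic_trinucleotide_content(perturb = 0.4, seed = 13)
  xr <- simulate_mutation_catalogue(S, e0, n_mut, genome_content = gc,
                                    region_content = rc,
                                    seed = stage_seed(seed, "region"))
  norm <- trinucleotide_normalize(xr, rc, gc)
  cosine <- cosine_similarity(as.numeric(norm), as.numeric(e0 %*% S))
  list(max_exposure_error = err, roundtrip_cosine = cosine)
}

#' Jackknife recovery of a planted region-specific signature enrichment
#'
#' A signature carries a `fold`-times higher mutation load in inactive than
#' in active promoter regions; the jackknifed activities should recover the
#' ratio.
#'
#' @param fold Planted activity fold change.
#' @param n_samples Samples in the cluster.
#' @param n_iter Jackknife iterations.
#' @param seed Seed.
#' @return List: `activity_ratio`, `fold_planted`, per-region activities.
#' @export
eval_region_jackknife <- function(fold = 3, n_samples = 8, n_iter = 100,
                                  seed = 1L) {
  S <- synthetic_signatures(6)
  gc <- synthetic_trinucleotide_content()
  content <- list(active_promoter = gc,
                  inactive_promoter = synthetic_trinucleotide_content(
                    perturb = 0.4, seed = 13))
  spec <- rbind(
    data.frame(region_class = "active_promoter", signature = c("S1", "S2"),
               mutations = c(300, 700)),
    data.frame(region_class = "inactive_promoter", signature = c("S1", "S2"),
               mutations = c(300 * fold, 600)))
  clusters <- list(C1 = sprintf("s%02d", seq_len(n_samples)))
  rcat <- simulate_region_catalogues(S, clusters, spec,
                                     region_content = content,
                                     genome_content = gc,
                                     seed = stage_seed(seed, "cat"))
  jk <- jackknife_activities(rcat$catalogues, S, region_content = content,
                             genome_content = gc, n_iter = n_iter,
                             seed = stage_seed(seed, "jk"))
  s1 <- jk[jk$signature == "S1", ]
  ratio <- s1$activity_mean[s1$region_class == "inactive_promoter"] /
    s1$activity_mean[s1$region_class == "active_promoter"]
  list(activity_ratio = ratio, fold_planted = fold, activities = s1)
}

#' Adenoma-versus-carcinoma burden pattern over replicates
#'
#' Carcinoma-only gains are planted; the expected pattern is a significant
#' gain-burden difference and a non-significant loss-burden difference
#' after read subsampling.
#'
#' @param n_rep Replicates.
#' @param n_adenoma,n_carcinoma Lesions per group.
#' @param n_peaks Peaks.
#' @param seed Seed.
#' @return List: `pattern_rate` (both conditions hold), `gain_sig_rate`,
#'   `loss_nonsig_rate`.
#' @export
eval_burden_pattern <- function(n_rep = 50, n_adenoma = 8, n_carcinoma = 24,
                                n_peaks = 1500, seed = 1L) {
  res <- with_seed(stage_seed(seed, "burden_eval"), {
    vapply(seq_len(n_rep), function(i) {
      base <- stats::rlnorm(n_peaks, log(50), 0.5)
      normal <- sapply(1:6, function(j) {
        stats::rnbinom(n_peaks, size = 20, mu = base)
      })
      rownames(normal) <- paste0("pk", seq_len(n_peaks))
      mkles <- function(depth, gains) {
        mu <- base * depth
        if (gains) mu[1:20] <- mu[1:20] * 3
        stats::rnbinom(n_peaks, size = 20, mu = mu)
      }
      counts <- cbind(sapply(seq_len(n_adenoma), function(j) mkles(1, FALSE)),
                      sapply(seq_len(n_carcinoma), function(j) mkles(2.5, TRUE)))
      colnames(counts) <- paste0("les", seq_len(ncol(counts)))
      rownames(counts) <- paste0("pk", seq_len(n_peaks))
      type <- rep(c("adenoma", "carcinoma"), c(n_adenoma, n_carcinoma))
      r <- burden_comparison(counts, type, normal, dispersion = 0.05,
                             seed = sample.int(2^30, 1))
      c(gain = r$p_gain < 0.05, loss = r$p_loss >= 0.05)
    }, logical(2))
  })
  list(pattern_rate = mean(res["gain", ] & res["loss", ]),
       gain_sig_rate = mean(res["gain", ]),
       loss_nonsig_rate = mean(res["loss", ]))
}
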