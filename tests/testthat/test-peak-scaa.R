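test_that("cut-site extraction applies the stated shifts and size classes", {
  fr <- data.frame(chrom = "chr1", start = c(100L, 1000L, 2000L),
                   end = c(200L, 1150L, 2400L), sample = "s1")
  cs <- shift_cut_sites(fr)
  ## insertion 100 -> nucleosome-free; 150 -> neither class; 400 -> nucleosome
  expect_equal(sort(unique(cs$insert_size)), c(100L, 400L))
  nf <- cs[cs$class == "nucleosome_free", ]
  expect_setequal(nf$pos, c(100L - 4L, 200L + 5L))
  nuc <- cs[cs$class == "nucleosome", ]
  expect_setequal(nuc$pos, c(2000L - 4L, 2400L + 5L))
  ## empty input
  empty <- shift_cut_sites(fr[0, ])
  expect_equal(nrow(empty), 0)
  ## clipping at the contig start warns and counts
  expect_warning(cs2 <- shift_cut_sites(data.frame(chrom = "chr1", start = 2L,
                                                   end = 90L)), "clipped")
  expect_equal(attr(cs2, "n_clipped"), 1L)
  expect_true(all(cs2$pos >= 0))
})

test_that("peak filtering and iterative merging match a naive oracle", {
  set.seed(10)
  for (i in 1:5) {
    mk <- function(n) {
      start <- sample.int(5000, n)
      data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE), start = start,
                 end = start + sample(100:400, n, TRUE),
                 q_value = runif(n, 1e-10, 5e-4),
                 enrichment = runif(n, 5, 20))
    }
    calls <- list(r1 = mk(20), r2 = mk(15), r3 = mk(15))
    res <- filter_and_merge_peaks(calls, min_tumour_regions = 0)
    pooled <- do.call(rbind, Map(function(df, nm) {
      df$source <- nm; df
    }, calls, names(calls)))
    oracle <- merge_brute(pooled)
    expect_equal(res$start, oracle$start)
    expect_equal(res$q_value, oracle$q_value)
    ## non-overlap invariant
    by_chr <- split(res, res$chrom)
    for (b in by_chr) {
      b <- b[order(b$start), ]
      if (nrow(b) > 1) expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
    }
  }
})

test_that("peak retention follows the region-support rule", {
  pk <- data.frame(chrom = "chr1", start = 100L, end = 300L,
                   q_value = 1e-8, enrichment = 10)
  ## three tumour regions -> retained
  r3 <- filter_and_merge_peaks(list(a = pk, b = pk, c = pk))
  expect_true(r3$retained)
  expect_equal(r3$support_tumour, 3L)
  ## exactly two tumour regions, no normal -> dropped
  r2 <- filter_and_merge_peaks(list(a = pk, b = pk))
  expect_false(r2$retained)
  ## normal panel support alone retains
  rn <- filter_and_merge_peaks(list(normal_panel = pk))
  expect_true(rn$retained)
  ## low-quality calls are filtered out before merging
  bad <- data.frame(chrom = "chr1", start = 1L, end = 100L,
                    q_value = 0.05, enrichment = 10)
  expect_equal(nrow(filter_and_merge_peaks(list(a = bad))), 0)
})

test_that("copy-number adjustment factor matches hand-derived values", {
  expect_equal(cn_adjust_factor(0, 5, 2), 1)
  expect_equal(cn_adjust_factor(0.7, 3, 3), 1)
  expect_equal(cn_adjust_factor(0.5, 4, 2), 1.5)
  expect_error(cn_adjust_factor(1, 2, 0), "degenerate")
  ## pooled factor is the read-weighted mean
  expect_equal(pooled_cn_adjust_factor(c(0.5, 0), c(4, 4), 2, c(100, 300)),
               (1.5 * 100 + 1 * 300) / 400)
})

test_that("TMM-style size factors satisfy their construction contracts", {
  set.seed(11)
  counts <- matrix(rnbinom(400 * 20, size = 10, mu = 50), 400, 20,
                   dimnames = list(NULL, paste0("s", 1:20)))
  same <- matrix(rep(counts[, 1], 5), ncol = 5,
                 dimnames = list(NULL, paste0("s", 1:5)))
  expect_equal(unname(size_factors(same)), rep(1, 5), tolerance = 1e-9)
  ## one doubled column: its factor doubles relative to the others
  counts2 <- counts
  counts2[, 3] <- counts2[, 3] * 2L
  f <- size_factors(counts2)
  expect_equal(unname(f[3] / median(f[-3])), 2, tolerance = 0.05)
  ## geometric mean normalized to 1
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)
  ## all-zero sample is a named error
  counts3 <- counts; counts3[, 2] <- 0L
  expect_error(size_factors(counts3), "s2")
})

test_that("the SCAA count test is offset-stable and directionally sound", {
  set.seed(12)
  yT <- rnbinom(8, size = 20, mu = 150)
  yN <- rnbinom(6, size = 20, mu = 50)
  offT <- log(runif(8, 0.5, 2)); offN <- log(runif(6, 0.5, 2))
  r1 <- test_scaa(yT, yN, offT, offN, dispersion = 0.05)
  ## doubling counts and size factors together leaves the estimate stable
  ## (exactly invariant in the Poisson limit; the NB variance function makes
  ## it approximate at finite dispersion)
  r2 <- test_scaa(yT * 2L, yN * 2L, offT + log(2), offN + log(2),
                  dispersion = 0.05)
  expect_equal(r1$lfc, r2$lfc, tolerance = 0.05)
  expect_equal(r1$direction, r2$direction)
  expect_equal(r1$direction, "gain")
  ## exact invariance under a pure offset shift
  r3 <- test_scaa(yT, yN, offT + log(2), offN + log(2), dispersion = 0.05)
  expect_equal(r1$lfc, r3$lfc, tolerance = 1e-8)
  expect_equal(r1$p, r3$p, tolerance = 1e-8)
})

test_that("global dispersion estimation is close on simulated counts", {
  set.seed(13)
  n <- 400; ns <- 12
  sf <- rlnorm(ns, 0, 0.3)
  mu0 <- rlnorm(n, log(60), 0.5)
  counts <- sapply(seq_len(ns), function(j) {
    rnbinom(n, size = 1 / 0.08, mu = mu0 * sf[j])
  })
  offs <- matrix(log(sf), n, ns, byrow = TRUE)
  est <- estimate_global_dispersion(counts, offs, rep("a", ns))
  expect_lt(abs(est - 0.08), 0.02)
})

test_that("recurrence applies the same-direction 20% rule", {
  res <- data.frame(
    patient = c(paste0("P", 1:6), paste0("P", 1:2), "P1"),
    peak_id = c(rep("pk1", 6), rep("pk2", 2), "pk3"),
    p = c(rep(0.001, 6), rep(0.001, 2), 0.5),
    direction = c(rep("gain", 6), rep("loss", 2), "gain"))
  rec <- recurrence(res, n_cases = 26, alpha = 0.01, min_frac = 0.2)
  ## 6/26 >= ceil(0.2*26) = 6 -> recurrent; 2/26 -> not; p > alpha -> absent
  expect_true(rec$recurrent[rec$peak_id == "pk1"])
  expect_false(rec$recurrent[rec$peak_id == "pk2"])
  expect_false("pk3" %in% rec$peak_id)
  expect_equal(nrow(recurrence(res[0, ], 26)), 0)
})

test_that("subclonality verdicts require replication and the gain filter", {
  set.seed(14)
  ## single-region samples are untestable
  r <- test_subclonality(rpois(4, 50), runif(4, 0.5, 1), rep("A", 4),
                         rep(0, 4), 0.05)
  expect_false(r$testable)
  ## a gain without a nearby called peak is demoted to clonal
  counts <- c(rnbinom(4, 20, mu = 300), rnbinom(4, 20, mu = 50))
  ev <- list(list(counts = counts, purity = runif(8, 0.5, 0.9),
                  region = rep(c("A", "B"), each = 4),
                  log_offsets = rep(0, 8), direction = "gain",
                  position = 5000, chrom = "chr1"))
  with_peak <- call_subclonality(ev, 0.05,
                                 called_peaks = data.frame(chrom = "chr1",
                                                           start = 4800L,
                                                           end = 5300L))
  no_peak <- call_subclonality(ev, 0.05,
                               called_peaks = data.frame(chrom = "chr1",
                                                         start = 9000L,
                                                         end = 9400L))
  expect_equal(with_peak$verdict, "subclonal")
  expect_equal(no_peak$verdict, "clonal")
})

test_that("expression association finds planted shifts and skips unannotated genes", {
  set.seed(15)
  ng <- 40; grp <- rep(c("normal", "non_altered", "altered"), each = 8)
  mu <- matrix(100, ng, 24)
  mu[1:8, grp == "altered"] <- 280
  expr <- matrix(rnbinom(ng * 24, size = 10, mu = mu), ng, 24,
                 dimnames = list(paste0("g", 1:ng), NULL))
  dirs <- stats::setNames(rep("gain", ng), rownames(expr))
  dirs[35:40] <- NA ## peaks with no annotated gene
  ea <- expression_association(expr, grp, dirs, dispersion = 0.1,
                               log_offsets = rep(0, 24))
  expect_equal(nrow(ea), 34)
  expect_gte(sum(ea$fdr[ea$gene %in% paste0("g", 1:8)] < 0.01), 7)
  expect_lte(sum(ea$fdr[ea$gene %in% paste0("g", 9:34)] < 0.05), 2)
})

test_that("expressed-gene filtering removes silent and purity-driven genes", {
  set.seed(16)
  ns <- 60
  purity <- runif(ns, 0.2, 0.9)
  patient <- rep(c("P1", "P2", "P3"), each = 20)
  tpm <- matrix(50 * 2^rnorm(3 * ns, 0, 0.1), 3, ns,
                dimnames = list(c("flat", "silent", "purity_neg"), NULL))
  tpm["silent", ] <- 0
  tpm["purity_neg", ] <- 2^(8 - 4 * purity + rnorm(ns, 0, 0.1))
  keep <- filter_expressed_genes(tpm, purity, patient)
  expect_true("flat" %in% keep)
  expect_false("silent" %in% keep)
  expect_false("purity_neg" %in% keep)
})

test_that("recurrence ranking is stable with and without CN adjustment", {
  ## near-diploid genomes with one small single-copy gain per patient:
  ## recurrence counts with and without the adjustment stay strongly
  ## rank-correlated. Strong or widespread CNAs are exactly the case the
  ## adjustment exists for, so they are excluded from this stability check;
  ## even so, a heterozygous gain in near-pure glands carries genuine signal
  ## for the unadjusted analysis, which bounds how high the correlation can
  ## be at single-gland purity.
  set.seed(17)
  co <- simulate_cohort(cohort_config(n_patients = 4, glands_per_region = 3,
                                      peak_count = 300, scaa_fraction = 0.1,
                                      ploidy = 2, nb_dispersion = 0.15,
                                      purity_range = c(0.5, 0.9), seed = 78))
  segs <- co$truth$segments
  segs$state <- 2L
  for (p in unique(segs$patient)) {
    sel <- which(segs$patient == p)
    segs$state[sel[which.min(segs$end[sel] - segs$start[sel])]] <- 3L
  }
  co$truth$segments <- segs
  pt <- simulate_peak_counts(co)
  sf <- size_factors(pt$counts)
  offs_cn <- matrix(0, nrow(pt$counts), ncol(pt$counts),
                    dimnames = dimnames(pt$counts))
  for (j in seq_len(nrow(co$samples))) {
    smp <- co$samples[j, ]
    pi_loc <- scaar:::segment_state_at(co$truth$segments, smp$patient,
                                       pt$peaks$chrom,
                                       as.integer((pt$peaks$start + pt$peaks$end) / 2))
    offs_cn[, j] <- log(sf[j] * cn_adjust_factor(smp$purity, pi_loc,
                                                 co$truth$ploidy[[smp$patient]]))
  }
  offs_plain <- matrix(log(sf), nrow(pt$counts), ncol(pt$counts), byrow = TRUE,
                       dimnames = dimnames(pt$counts))
  disp <- co$config$nb_dispersion
  res_cn <- call_scaas(pt$counts, co$samples, offs_cn, disp)
  res_plain <- call_scaas(pt$counts, co$samples, offs_plain, disp)
  n_cn <- tapply(res_cn$p <= 0.01, res_cn$peak_id, sum)
  n_plain <- tapply(res_plain$p <= 0.01, res_plain$peak_id, sum)
  expect_gt(cor(n_cn, n_plain[names(n_cn)], method = "spearman"), 0.8)
  ## every planted clonal SCAA keeps its recurrence count under adjustment
  planted <- pt$truth$peak_id[pt$truth$status != "unchanged" &
                                !pt$truth$subclonal]
  expect_true(all(n_cn[planted] > 0 | n_plain[planted] == 0))
})
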