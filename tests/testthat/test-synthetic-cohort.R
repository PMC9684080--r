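test_that("cohort simulation is deterministic and respects the design", {
  cfg <- cohort_config(n_patients = 2, regions_per_tumour = 4,
                       glands_per_region = 5, peak_count = 50, seed = 7)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$samples, co2$samples)
  expect_identical(co1$truth$segments, co2$truth$segments)
  ## 2 patients x (4 regions x 5 glands + 5 normals) = 50 samples
  expect_equal(nrow(co1$samples), 50)
  expect_true(all(co1$samples$purity[co1$samples$region == "E"] == 0))
  tum <- co1$samples$region != "E"
  expect_true(all(co1$samples$purity[tum] >= 0.3 & co1$samples$purity[tum] <= 0.95))

  co_pure <- simulate_cohort(cohort_config(n_patients = 1, peak_count = 10,
                                           purity_range = c(1, 1), seed = 1))
  expect_true(all(co_pure$samples$purity[co_pure$samples$region != "E"] == 1))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(cohort_config(glands_per_region = 1), "glands_per_region")
  expect_error(cohort_config(purity_range = c(0.5, 1.5)), "purity_range")
  expect_error(cohort_config(scaa_fraction = 1.2), "scaa_fraction")
  expect_error(cohort_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(simulate_cohort(list()), "cohort_config")
})

test_that("allele counts follow the purity-multiplicity binomial model", {
  ## rho = 0 -> no alt reads at clonal sites
  co0 <- simulate_cohort(cohort_config(n_patients = 1, peak_count = 10,
                                       purity_range = c(0, 0), seed = 3))
  al0 <- simulate_allele_counts(co0, n_sites = 50)
  expect_true(all(al0$alt_count == 0))

  ## rho = 1, m = 1, c = 2 -> VAF 0.5; Monte-Carlo check of the mean
  co1 <- simulate_cohort(cohort_config(n_patients = 1, ploidy = 2,
                                       purity_range = c(1, 1), peak_count = 10,
                                       sequencing_depth = 50, seed = 4))
  al1 <- simulate_allele_counts(co1, n_sites = 3000)
  het <- al1$multiplicity == 1 & al1$copy_number == 2 &
    al1$sample == al1$sample[1]
  vaf <- al1$alt_count[het] / (al1$ref_count[het] + al1$alt_count[het])
  expect_lt(abs(mean(vaf, na.rm = TRUE) - 0.5), 0.01)

  ## rho = 0.5, m = 1, c = 3 -> expected VAF 0.2 (= 0.5 / (1.5 + 1))
  expect_equal(expected_vaf(0.5, 1, 3), 0.2)
  n <- rpois(1e5, 30)
  k <- rbinom(1e5, n, expected_vaf(0.5, 1, 3))
  expect_lt(abs(mean(k / ifelse(n == 0, NA, n), na.rm = TRUE) - 0.2), 0.005)
})

test_that("peak counts reproduce the copy-number-scaled NB mean structure", {
  ## normal glands: mean = sf * S_N regardless of locus copy number
  co <- simulate_cohort(cohort_config(n_patients = 1, glands_per_region = 4,
                                      peak_count = 400, scaa_fraction = 0,
                                      nb_dispersion = 0.05, seed = 11))
  pt <- simulate_peak_counts(co)
  norm <- co$samples$sample[co$samples$region == "E"]
  expected <- outer(pt$baseline, pt$size_factors_true[norm])
  ratio <- sum(pt$counts[, norm]) / sum(expected)
  expect_lt(abs(ratio - 1), 0.05)

  ## planted gain effect at rho = 1: tumour/normal mean ratio = effect * pi / psi
  co2 <- simulate_cohort(cohort_config(n_patients = 1, glands_per_region = 4,
                                       purity_range = c(1, 1), ploidy = 2,
                                       peak_count = 800, scaa_fraction = 0.3,
                                       subclonal_fraction = 0, gain_effect = 3,
                                       nb_dispersion = 0.05, seed = 12))
  pt2 <- simulate_peak_counts(co2, affected_fraction_range = c(1, 1))
  tum <- co2$samples$sample[co2$samples$region != "E"]
  nrm <- co2$samples$sample[co2$samples$region == "E"]
  gained <- which(pt2$truth$status == "gained")
  pi_loc <- scaar:::segment_state_at(co2$truth$segments, "P01",
                                     pt2$peaks$chrom[gained],
                                     as.integer((pt2$peaks$start[gained] +
                                                   pt2$peaks$end[gained]) / 2))
  obs <- rowSums(pt2$counts[gained, tum, drop = FALSE]) /
    sum(pt2$size_factors_true[tum]) /
    (rowSums(pt2$counts[gained, nrm, drop = FALSE]) /
       sum(pt2$size_factors_true[nrm]))
  expect_lt(abs(mean(obs / (3 * pi_loc / 2)) - 1), 0.1)
})

test_that("low-pass bins follow the purity-ploidy log ratio model", {
  ## rho = 1, diploid flat genome: all bins ~ 0
  co <- simulate_cohort(cohort_config(n_patients = 1, purity_range = c(1, 1),
                                      ploidy = 2, peak_count = 10, seed = 5))
  ## force a flat genome to isolate the formula
  co$truth$segments$state <- 2L
  lp0 <- simulate_lowpass_bins(co, noise_sd = 0)
  expect_lt(max(abs(lp0$bins$log2ratio)), 1e-12)

  ## gain to 3 at rho = 1, psi = 2: uncentred bin mean = log2(1.5)
  co$truth$segments$state <- 2L
  co$truth$segments$state[1] <- 3L
  lp1 <- simulate_lowpass_bins(co, noise_sd = 0,
                               samples = co$samples$sample[1])
  seg1 <- co$truth$segments[1, ]
  in_seg <- lp1$bins$contig == seg1$contig & lp1$bins$start < seg1$end &
    lp1$bins$end > seg1$start
  uncentred <- lp1$bins$log2ratio + lp1$medians[[co$samples$sample[1]]]
  expect_equal(unique(round(uncentred[in_seg], 10)), round(log2(1.5), 10))
})

test_that("mutation catalogues mix signatures and respect region content", {
  S <- synthetic_signatures(6)
  expect_equal(rowSums(S), rep(1, 6), ignore_attr = TRUE)

  ## single signature at genome content: catalogue converges to the profile
  cat1 <- simulate_mutation_catalogue(S, c(1, 0, 0, 0, 0, 0), 1e5, seed = 2)
  expect_gte(cosine_similarity(as.numeric(cat1), as.numeric(S[1, ])), 0.99)

  expect_equal(sum(simulate_mutation_catalogue(S, c(1, 0, 0, 0, 0, 0), 0)), 0)

  ## 50/50 mixture of block-supported signatures splits channel mass evenly
  cat2 <- simulate_mutation_catalogue(S, c(0.5, 0.5, 0, 0, 0, 0), 1e5, seed = 3)
  block1 <- S[1, ] > 0.001
  frac <- sum(cat2[block1]) / sum(cat2)
  expect_lt(abs(frac - 0.5), 0.01)

  expect_error(simulate_mutation_catalogue(S, c(0.7, 0.2, 0, 0, 0, 0), 100),
               "sum to 1")
  expect_error(simulate_mutation_catalogue(S, c(1.2, -0.2, 0, 0, 0, 0), 100),
               "non-negative")
})

test_that("file formats round-trip losslessly", {
  co <- small_cohort()
  tf <- simulate_tf_sites(co, n_tf = 2, sites_per_tf = 20)
  fr <- simulate_fragments(co, tf, background_frags = 200)
  fr <- fr[1:500, ]
  f1 <- withr::local_tempfile(fileext = ".bed")
  write_fragments(fr, f1)
  expect_equal(read_fragments(f1), fr, ignore_attr = TRUE)

  al <- simulate_allele_counts(co, n_sites = 20)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_allele_counts(al, f2)
  back <- read_allele_counts(f2)
  expect_equal(back$alt_count, al$alt_count)
  expect_equal(back$clonal_flag, al$clonal_flag)

  pt <- simulate_peak_counts(co)
  pref <- withr::local_tempfile()
  write_peak_table(pt, pref)
  back_pt <- read_peak_table(pref)
  expect_equal(back_pt$counts, pt$counts)
  expect_equal(back_pt$peaks$start, pt$peaks$start)

  lp <- simulate_lowpass_bins(co, samples = co$samples$sample[1:2])
  f3 <- withr::local_tempfile(fileext = ".bed")
  write_bins(lp$bins, f3)
  expect_equal(read_bins(f3)$log2ratio, lp$bins$log2ratio)

  cfg <- cohort_config(n_patients = 3, seed = 9)
  f4 <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_config(cfg, f4)
  expect_equal(read_cohort_config(f4), cfg)
})

test_that("planted effects are retrievable from ground truth by identifier", {
  co <- small_cohort(seed = 19, scaa_fraction = 0.2)
  pt <- simulate_peak_counts(co)
  tr <- pt$truth
  planted <- tr[tr$status != "unchanged", ]
  expect_gt(nrow(planted), 0)
  expect_true(all(planted$peak_id %in% pt$peaks$peak_id))
  expect_true(all(nzchar(planted$affected_patients)))
  ## clonal alterations affect all tumour regions
  clonal <- planted[!planted$subclonal, ]
  expect_true(all(clonal$affected_regions == "A,B,C,D"))
  tf <- simulate_tf_sites(co)
  expect_true(all(names(tf$truth) %in% unique(tf$sites$tf)))
})

test_that("stage seeds are stable and distinct across stages", {
  expect_identical(stage_seed(1, "fragments"), stage_seed(1, "fragments"))
  expect_false(stage_seed(1, "fragments") == stage_seed(1, "peaks"))
  expect_false(stage_seed(1, "peaks") == stage_seed(2, "peaks"))
  expect_true(stage_seed(.Machine$integer.max, "x") < 2^31)
})
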