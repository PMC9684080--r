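test_that("insertion matrix equals a brute-force tally on tiny input", {
  set.seed(20)
  sites <- data.frame(chrom = "chr1", center = c(10000L, 20000L, 30000L,
                                                 42000L, 55000L),
                      strand = c("+", "-", "+", "+", "-"))
  start <- as.integer(sample(5000:60000, 100))
  fr <- data.frame(chrom = "chr1", start = start,
                   end = start + as.integer(sample(c(60, 80, 120, 200, 400),
                                                   100, TRUE)))
  m <- build_insertion_matrix(fr, sites)
  oracle <- insertion_matrix_brute(fr, sites)
  expect_equal(unclass(m), oracle, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("uniform background vanishes after flank subtraction", {
  set.seed(21)
  sites <- data.frame(chrom = "chr1", center = seq(50000L, 950000L, 50000L),
                      strand = "+")
  start <- as.integer(runif(40000, 1, 1e6))
  fr <- data.frame(chrom = "chr1", start = start, end = start + 80L)
  m <- build_insertion_matrix(fr, sites)
  block <- unclass(m)[attr(m, "size_breaks")[-1] <= 120, ]
  expect_lt(abs(mean(block)), 3 * sd(block) / sqrt(length(block)))
})

test_that("planted central enrichment appears only in the central block", {
  set.seed(22)
  sites <- data.frame(chrom = "chr1", center = seq(50000L, 950000L, 50000L),
                      strand = "+")
  bg_start <- as.integer(runif(20000, 1, 1e6))
  hit_site <- sample(sites$center, 4000, TRUE)
  hit_start <- as.integer(hit_site + rnorm(4000, 0, 30) - 35)
  fr <- data.frame(chrom = "chr1", start = c(bg_start, hit_start),
                   end = c(bg_start, hit_start) + 70L)
  m <- build_insertion_matrix(fr, sites)
  ds <- attr(m, "distances"); sb <- attr(m, "size_breaks")
  central <- unclass(m)[sb[-1] <= 120, abs(ds) <= 100]
  flank <- unclass(m)[sb[-1] <= 120, abs(ds) >= 750]
  expect_gt(mean(central), 10 * abs(mean(flank)))
})

test_that("differential signal is zero at identity and antisymmetric", {
  set.seed(23)
  sites <- data.frame(chrom = "chr1", center = c(10000L, 30000L), strand = "+")
  start <- as.integer(runif(2000, 1, 50000))
  fr <- data.frame(chrom = "chr1", start = start, end = start + 60L)
  m1 <- build_insertion_matrix(fr, sites)
  fr2 <- fr; fr2$start <- fr2$start + 5L; fr2$end <- fr2$end + 5L
  m2 <- build_insertion_matrix(fr2, sites)
  expect_equal(differential_signal(m1, m1), 0)
  expect_equal(differential_signal(m1, m2), -differential_signal(m2, m1))
  m3 <- build_insertion_matrix(fr, sites, flank = 900)
  expect_error(differential_signal(m1, m3), "grids")
})

test_that("signal regression recovers exact and noisy planted coefficients", {
  ## exact linear case: signal = purity * beta, no TSSe effects
  df <- expand.grid(patient = c("P1", "P2"), i = 1:6)
  df$purity <- runif(nrow(df))
  df$tsse <- 0; df$tsse_nf <- 0; df$reads <- 1e6
  beta <- c(P1 = 2.5, P2 = -1.25)
  df$signal <- beta[as.character(df$patient)] * df$purity
  cf <- regress_tf_signal(df)
  expect_equal(stats::setNames(cf$coefficient, cf$group), beta,
               tolerance = 1e-9)

  ## opposite-sign effects recovered under 10% noise
  set.seed(24)
  ok <- 0
  for (i in 1:25) {
    df$signal <- beta[as.character(df$patient)] * df$purity +
      rnorm(nrow(df), 0, 0.25)
    cf <- regress_tf_signal(df)
    ok <- ok + all(sign(cf$coefficient[match(c("P1", "P2"), cf$group)]) ==
                     sign(beta))
  }
  expect_equal(ok, 25)

  ## equal weights and sqrt-read weights agree on homoscedastic data
  df$reads <- runif(nrow(df), 1e5, 1e7)
  df$signal <- beta[as.character(df$patient)] * df$purity
  cf2 <- regress_tf_signal(df)
  expect_equal(stats::setNames(cf2$coefficient, cf2$group), beta,
               tolerance = 1e-9)
})

test_that("coefficient clustering separates planted blocks", {
  set.seed(25)
  n_pat <- 8
  coefs <- cbind(matrix(rnorm(n_pat * 5, 2, 0.2), n_pat, 5),
                 matrix(rnorm(n_pat * 5, -2, 0.2), n_pat, 5))
  colnames(coefs) <- paste0("TF", 1:10)
  cl <- cluster_tf_coefficients(coefs, top_k = 10, k_clusters = 2)
  expect_equal(length(unique(cl$clusters[paste0("TF", 1:5)])), 1)
  expect_equal(length(unique(cl$clusters[paste0("TF", 6:10)])), 1)
  expect_false(cl$clusters[["TF1"]] == cl$clusters[["TF10"]])
  ## duplicated columns always co-cluster; linkage heights non-decreasing
  coefs2 <- coefs; coefs2[, 2] <- coefs2[, 1]
  cl2 <- cluster_tf_coefficients(coefs2, top_k = 10, k_clusters = 3)
  expect_equal(cl2$clusters[["TF1"]], cl2$clusters[["TF2"]])
  expect_true(all(diff(cl2$tree$height) >= -1e-12))
  ## k above the number of TFs falls back to all with a message
  expect_message(cluster_tf_coefficients(coefs, top_k = 50), "using all")
})

test_that("TF site strata partition sites and respect homotypic spacing", {
  co <- small_cohort(seed = 31)
  tf <- simulate_tf_sites(co, n_tf = 5, sites_per_tf = 80)
  expect_false(any(is.na(tf$sites$stratum)))
  for (tfn in unique(tf$sites$tf)) {
    s <- tf$sites[tf$sites$tf == tfn, ]
    for (ct in unique(s$chrom)) {
      pos <- sort(s$center[s$chrom == ct])
      if (length(pos) > 1) expect_true(all(diff(pos) >= 1000))
    }
  }
})
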