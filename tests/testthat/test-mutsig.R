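test_that("exposure fitting recovers pure and mixed catalogues", {
  S <- synthetic_signatures(6)
  ## exact single signature
  f1 <- fit_exposures(round(S[3, ] * 1e5), S, lambda = 0)
  expect_gt(f1$exposures[["S3"]], 0.99)
  ## empty catalogue flags and returns zeros
  f0 <- fit_exposures(rep(0, 96), S)
  expect_true(f0$empty)
  expect_equal(sum(f0$exposures), 0)
})

test_that("lambda = 0 fit equals NNLS and a simplex grid search", {
  skip_if_not_installed("pracma")
  S <- synthetic_signatures(6)
  set.seed(30)
  for (i in 1:10) {
    e0 <- runif(6); e0 <- e0 / sum(e0)
    x <- as.numeric(rmultinom(1, 5e4, as.numeric(e0 %*% S)))
    f <- fit_exposures(x, S, lambda = 0)
    nn <- pracma::lsqnonneg(t(S), x / sum(x))$x
    expect_equal(unname(f$exposures), nn / sum(nn), tolerance = 1e-6)
  }
  ## two-signature simplex: exhaustive grid oracle at resolution 0.001
  S2 <- S[1:2, ]
  x <- as.numeric(rmultinom(1, 5e4, as.numeric(c(0.6, 0.4) %*% S2)))
  grid <- seq(0, 1, 0.001)
  xs <- x / sum(x)
  sse <- vapply(grid, function(a) {
    sum((xs - as.numeric(c(a, 1 - a) %*% S2))^2)
  }, numeric(1))
  best <- grid[which.min(sse)]
  f2 <- fit_exposures(x, S2, lambda = 0)
  expect_lt(abs(f2$exposures[["S1"]] - best), 0.005)
})

test_that("exposure residual shrinks with catalogue size under the model", {
  S <- synthetic_signatures(4)
  e0 <- c(0.4, 0.3, 0.2, 0.1)
  set.seed(31)
  res <- vapply(c(500, 5000, 50000), function(n) {
    x <- as.numeric(rmultinom(1, n, as.numeric(e0 %*% S)))
    fit_exposures(x, S, lambda = 0)$residual
  }, numeric(1))
  expect_true(all(diff(res) < 0))
})

test_that("trinucleotide normalization is exact and guards its inputs", {
  gc <- synthetic_trinucleotide_content()
  x <- round(runif(96, 0, 50))
  names(x) <- sbs96_channels()
  expect_equal(trinucleotide_normalize(x, gc, gc), x, ignore_attr = TRUE)
  expect_equal(trinucleotide_normalize(x, gc / 2, gc), x * 2,
               ignore_attr = TRUE, tolerance = 1e-12)
  bad <- gc; bad[1] <- 0
  xx <- x; xx[] <- 1
  expect_error(trinucleotide_normalize(xx, bad, gc), "zero region frequency")
  expect_error(trinucleotide_normalize(x, gc[1:10], gc), "missing contexts")
})

test_that("region re-weighted catalogues round-trip through normalization", {
  S <- synthetic_signatures(6)
  gc <- synthetic_trinucleotide_content()
  rc <- synthetic_trinucleotide_content(perturb = 0.4, seed = 13)
  e0 <- c(0.7, 0.3, 0, 0, 0, 0)
  x <- simulate_mutation_catalogue(S, e0, 1e5, genome_content = gc,
                                   region_content = rc, seed = 6)
  mix <- as.numeric(e0 %*% S)
  expect_lt(cosine_similarity(as.numeric(x), mix), 0.99) ## bias is real
  norm <- trinucleotide_normalize(x, rc, gc)
  expect_gte(cosine_similarity(as.numeric(norm), mix), 0.99)
})

test_that("patient clustering on cosine distance separates exposure groups", {
  E <- rbind(matrix(rep(c(1, 0, 0, 0, 0, 0), 4), ncol = 6, byrow = TRUE),
             matrix(rep(c(0, 0, 1, 0, 0, 0), 4), ncol = 6, byrow = TRUE))
  rownames(E) <- paste0("p", 1:8)
  cl <- cluster_patients(E, k = 2, seed = 5)
  expect_equal(length(unique(cl[1:4])), 1)
  expect_equal(length(unique(cl[5:8])), 1)
  expect_false(cl[["p1"]] == cl[["p8"]])
  expect_error(cluster_patients(E, k = 0), "k")
  ## identical vectors: distance 0, one effective cluster
  E2 <- matrix(rep(c(0.5, 0.5, 0, 0, 0, 0), 4), ncol = 6, byrow = TRUE)
  rownames(E2) <- paste0("q", 1:4)
  expect_equal(length(unique(cluster_patients(E2, k = 1, seed = 1))), 1)
})

test_that("jackknife activities are seed-stable and respect cluster minima", {
  S <- synthetic_signatures(4)
  spec <- data.frame(region_class = "coding", signature = "S1",
                     mutations = 500)
  cl <- list(C1 = paste0("s", 1:5), C2 = paste0("t", 1:2))
  rcat <- simulate_region_catalogues(S, cl, spec, seed = 9)
  expect_message(
    jk1 <- jackknife_activities(rcat$catalogues, S, n_iter = 20, seed = 3),
    "skipped")
  jk2 <- suppressMessages(
    jackknife_activities(rcat$catalogues, S, n_iter = 20, seed = 3))
  expect_equal(jk1, jk2)
  expect_false("C2" %in% jk1$cluster)
  ## single-signature truth: exposure 1 with zero-width interval
  s1 <- jk1[jk1$signature == "S1", ]
  expect_equal(s1$exposure_mean, 1, tolerance = 1e-9)
  expect_equal(s1$exposure_hi - s1$exposure_lo, 0, tolerance = 1e-9)
  ## sample order does not change the estimate
  perm <- rcat$catalogues[rev(seq_len(nrow(rcat$catalogues))), ]
  jk3 <- suppressMessages(jackknife_activities(perm, S, n_iter = 20, seed = 3))
  expect_equal(jk3$exposure_mean, jk1$exposure_mean, tolerance = 1e-9)
})

test_that("subset attribution tracks the background spectrum", {
  S <- synthetic_signatures(6)
  bg <- c(0.6, 0.3, 0.1, 0, 0, 0)
  set.seed(33)
  mix <- as.numeric(bg %*% S)
  from_bg <- as.numeric(rmultinom(1, 1e4, mix))
  att <- attribute_mutation_subset(from_bg, S, bg)
  expect_gte(att$cosine, 0.97)
  ## a subset from a signature absent from the background scores lower
  alien <- as.numeric(rmultinom(1, 1e4, as.numeric(S[6, ])))
  att2 <- attribute_mutation_subset(alien, S, bg)
  expect_lt(att2$cosine, att$cosine)
  ## identical spectra have cosine 1; empty subsets flag NA
  expect_equal(cosine_similarity(mix, mix), 1)
  expect_true(is.na(attribute_mutation_subset(rep(0, 96), S, bg)$cosine))
})
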