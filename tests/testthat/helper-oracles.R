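## Independent brute-force oracles used across the suite. These are written
## deliberately naively and share no code with the package internals.

## Two-sided Fisher exact p by full enumeration of tables with fixed margins.
fisher_brute <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) {
    choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1)
  }, numeric(1))
  p_obs <- probs[a - lo + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## Naive re-implementation of iterative most-significant-first merging.
merge_brute <- function(df) {
  df <- df[order(df$q_value), ]
  out <- NULL
  while (nrow(df) > 0) {
    top <- df[1, ]
    ov <- df$chrom == top$chrom & df$start < top$end & df$end > top$start
    rec <- top[, c("chrom", "start", "end", "q_value")]
    rec$sources <- paste(sort(unique(df$source[ov])), collapse = ",")
    out <- rbind(out, rec)
    df <- df[!ov, , drop = FALSE]
  }
  out[order(out$chrom, out$start), ]
}

## Per-site binomial NLL, coded independently.
nll_brute <- function(rho, k, n, m, cc) {
  tot <- 0
  for (i in seq_along(k)) {
    if (n[i] == 0) next
    p <- rho * m[i] / (rho * cc[i] + 2 - 2 * rho)
    tot <- tot - (lchoose(n[i], k[i]) + k[i] * log(p) + (n[i] - k[i]) * log(1 - p))
  }
  tot
}

## Brute-force insertion-matrix tally for a handful of sites and fragments.
insertion_matrix_brute <- function(fragments, sites, flank = 1000,
                                   size_range = c(20, 620), size_bin = 5) {
  breaks <- seq(size_range[1], size_range[2] + size_bin, by = size_bin)
  M <- matrix(0, length(breaks) - 1L, 2 * flank + 1)
  totals <- numeric(length(breaks) - 1L)
  for (i in seq_len(nrow(fragments))) {
    sz <- fragments$end[i] - fragments$start[i]
    if (sz < size_range[1] || sz > size_range[2]) next
    row <- findInterval(sz, breaks, rightmost.closed = TRUE)
    totals[row] <- totals[row] + 2
    for (pos in c(fragments$start[i] - 4L, fragments$end[i] + 5L)) {
      for (j in seq_len(nrow(sites))) {
        if (sites$chrom[j] != fragments$chrom[i]) next
        d <- pos - sites$center[j]
        if (sites$strand[j] == "-") d <- -d
        if (abs(d) <= flank) M[row, d + flank + 1] <- M[row, d + flank + 1] + 1
      }
    }
  }
  M <- M / ifelse(totals > 0, totals, NA)
  M[is.na(M)] <- 0
  dists <- -flank:flank
  M - rowMeans(M[, abs(dists) >= 750 & abs(dists) <= 1000, drop = FALSE])
}

## Small default cohort shared by several tests.
small_cohort <- function(seed = 42, ...) {
  simulate_cohort(cohort_config(n_patients = 2, glands_per_region = 3,
                                peak_count = 120, seed = seed, ...))
}
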