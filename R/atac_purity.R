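## Tumour purity estimation from allele counts of clonal SNVs in ATAC reads.
##
## The fraction of tumour cells rho in a gland is estimated from the variant
## allele fractions of clonal somatic SNVs observed in ATAC-seq reads. At a
## clonal site with multiplicity m (mutated copies per tumour cell) and total
## tumour copy number c, the alternative-allele read count is binomial with
## success probability
##
##   p(rho) = rho * m / (rho * c + 2 - 2 * rho)
##
## (contaminating normal cells contribute two reference copies). rho is
## estimated by minimizing the summed binomial negative log-likelihood over
## an exhaustive grid on [0, 1].

#' Expected variant allele fraction at a clonal site
#'
#' @param rho Purity in `[0, 1]`.
#' @param m Multiplicity (mutated copies per tumour cell), integer >= 1.
#' @param c_tot Total copy number in tumour cells, integer >= m.
#' @return Expected VAF `rho * m / (rho * c_tot + 2 - 2 * rho)`, strictly
#'   increasing in `rho` for fixed `m`, `c_tot`.
#' @export
expected_vaf <- function(rho, m, c_tot) {
  stopifnot(all(rho >= 0 & rho <= 1), all(m >= 1), all(c_tot >= m))
  denom <- rho * c_tot + 2 - 2 * rho
  if (any(denom == 0)) {
    stop("degenerate site: zero total copies (rho = 1 and c = 0)")
  }
  rho * m / denom
}

#' Binomial negative log-likelihood of a purity value
#'
#' Sum over sites of `-log Binom(k | n, p(rho))`. Sites with zero depth
#' contribute 0; an impossible observation (`p` in {0, 1} contradicted by
#' `k`) yields `+Inf`.
#'
#' @param rho Purity.
#' @param k Alt read counts per site.
#' @param n Depths per site.
#' @param m Multiplicities per site.
#' @param c_tot Total copy numbers per site.
#' @return Scalar negative log-likelihood.
#' @export
purity_nll <- function(rho, k, n, m, c_tot) {
  if (length(k) == 0) stop("empty site set")
  stopifnot(length(k) == length(n), length(k) == length(m),
            length(k) == length(c_tot), all(k <= n))
  p <- expected_vaf(rho, m, c_tot)
  ll <- stats::dbinom(k, n, p, log = TRUE)
  ll[n == 0] <- 0
  -sum(ll)
}

#' Maximum-likelihood purity estimate for one sample
#'
#' Exhaustive grid search of the binomial negative log-likelihood over
#' `rho` in `[0, 1]`; ties are broken toward smaller `rho`. A 95% profile
#' likelihood interval is read off the curve at a half-width of 1.92
#' (chi-squared with 1 df).
#'
#' @param alleles Data frame with columns alt_count, ref_count (or depth),
#'   multiplicity, copy_number, and optionally clonal_flag (only clonal
#'   sites are used).
#' @param min_depth Sites with depth below this are excluded (ATAC coverage
#'   per site is low and shallow sites carry little information).
#' @param grid_step Grid resolution for `rho`.
#' @return Object of class `purity_estimate`: list with `rho_hat`, `ci_95`,
#'   `nll_curve` (data frame rho, nll), `n_sites_used`, `n_sites_excluded`.
#' @export
estimate_purity <- function(alleles, min_depth = 5, grid_step = 0.001) {
  stopifnot(is.data.frame(alleles))
  if ("clonal_flag" %in% names(alleles)) {
    alleles <- alleles[as.logical(alleles$clonal_flag), , drop = FALSE]
  }
  depth <- if ("depth" %in% names(alleles)) alleles$depth else
    alleles$ref_count + alleles$alt_count
  n_total <- nrow(alleles)
  keep <- depth >= min_depth & alleles$copy_number >= 1
  alleles <- alleles[keep, , drop = FALSE]
  depth <- depth[keep]
  if (nrow(alleles) == 0 || all(depth == 0)) {
    stop("purity estimation failed: no usable clonal sites with positive depth")
  }
  grid <- seq(0, 1, by = grid_step)
  nll <- vapply(grid, purity_nll, numeric(1),
                k = alleles$alt_count, n = depth,
                m = alleles$multiplicity, c_tot = alleles$copy_number)
  i_min <- which.min(nll) ## which.min takes the first, i.e. smallest rho
  inside <- grid[nll <= nll[i_min] + 1.92]
  structure(list(
    rho_hat = grid[i_min],
    ci_95 = c(min(inside), max(inside)),
    nll_curve = data.frame(rho = grid, nll = nll),
    n_sites_used = nrow(alleles),
    n_sites_excluded = n_total - nrow(alleles)
  ), class = "purity_estimate")
}

#' @export
print.purity_estimate <- function(x, ...) {
  cat(sprintf("ATAC purity estimate: rho = %.3f [%.3f, %.3f], %d sites\n",
              x$rho_hat, x$ci_95[1], x$ci_95[2], x$n_sites_used))
  invisible(x)
}

#' Per-sample purity estimates for a whole allele-count table
#'
#' @param alleles Long allele-count table with a `sample` column, as written
#'   by [write_allele_counts()].
#' @inheritParams estimate_purity
#' @return Data frame sample, rho_hat, ci_low, ci_high, n_sites.
#' @export
estimate_purity_all <- function(alleles, min_depth = 5, grid_step = 0.001) {
  stopifnot("sample" %in% names(alleles))
  out <- lapply(split(alleles, alleles$sample), function(a) {
    est <- estimate_purity(a, min_depth = min_depth, grid_step = grid_step)
    data.frame(sample = a$sample[1], rho_hat = est$rho_hat,
               ci_low = est$ci_95[1], ci_high = est$ci_95[2],
               n_sites = est$n_sites_used, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
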