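# scaar

Somatic chromatin accessibility alterations (SCAAs) from multi-region,
single-gland ATAC-seq of colorectal tumours.

Colorectal cancers are organized into glands, each of which is close to a
single clone; profiling individual glands from several regions of a tumour
(regions A–D, plus a distant normal region E) gives genome and epigenome
measurements at single-clone resolution. `scaar` implements the bespoke
computational stages such a study needs, together with a synthetic cohort
generator with full ground truth, so that every stage can be validated
end to end:

* **ATAC purity estimation.** At a clonal SNV with multiplicity *m* and
  tumour copy number *c*, the variant allele fraction in ATAC reads is
  binomial with success probability
  *p*(ρ) = ρ·*m* / (ρ·*c* + 2 − 2ρ),
  where ρ is the tumour-cell fraction of the gland. ρ is estimated by
  exhaustive grid minimization of the binomial negative log-likelihood over
  all clonal sites, with a profile-likelihood 95% interval.
* **Low-pass copy number.** Binned log2 coverage ratios are segmented
  jointly across a patient's samples (penalized least squares; exact
  dynamic programming per contig). For each candidate purity, the
  continuous copy number of a segment is
  (2^r·(2(1−ρ) + ρΨ_t) − 2(1−ρ)) / ρ
  with Ψ_t the integer tumour ploidy; purity is the best local minimum of
  the length-weighted squared distance to the nearest non-negative integer
  state.
* **SCAA detection.** Peak calls are filtered (q < 0.1%, enrichment > 4,
  top 20,000) and merged iteratively; insertion counts are modelled with a
  negative-binomial GLM (fixed global dispersion, Cox–Reid adjusted
  estimate) whose offset combines TMM-style size factors with the
  copy-number adjustment
  S = S_N·(2(1−ρ) + πρ) / (2(1−ρ) + ψρ).
  Per-patient calls at P ≤ 0.01 versus the normal pool are tallied into
  cross-patient recurrence (same-direction significance in ≥ 20% of cases);
  subclonality is a likelihood-ratio test of `~ purity + region` against
  `~ purity`, with a 500-bp called-peak filter for gains; expression
  association contrasts altered versus non-altered patients with matched
  RNA counts.
* **TF footprints.** Insertions around TF binding sites are tabulated into
  insertion-size × distance matrices (5-bp size bins, ±1,000 bp),
  normalized per size bin by the genome-wide insertion count, and
  background-corrected on the 750–1,000 bp flanks. The tumour−normal
  difference integrated over sizes 25–120 bp and distances ±100 bp is
  regressed on `tsse * tsse_nf + purity:patient` (weights √reads); the
  purity coefficients are clustered (Euclidean, complete linkage).
* **Mutational signatures.** Exposures of a fixed 96-channel signature set
  are fitted by non-negative L1-regularized least squares (coordinate
  descent); patients are clustered by k-means on 1 − cosine similarity of
  exposures; region-stratified activities are estimated by 100× jackknife
  over 90% of samples with trinucleotide-content normalization of each
  region's catalogue.
* **Cohort statistics.** Two-sided Fisher exact tests of driver-mutation
  frequencies, microsatellite-instability classification (> 30% mutated
  microsatellites), adenoma-versus-carcinoma SCAA burden after
  hypergeometric read subsampling, and heritability analyses
  (within- versus between-region SCAA divergence with covariate control and
  a permutation p-value; partial Mantel correlation of genetic and
  epigenetic distance controlling for purity).

## Worked example

Simulate a small two-patient cohort, estimate per-gland purity from ATAC
allele counts, and call recurrent SCAAs against the normal pool:

```r
library(scaar)

cfg <- cohort_config(n_patients = 2, glands_per_region = 3, peak_count = 500,
                     scaa_fraction = 0.1, purity_range = c(0.5, 0.95), seed = 42)
cohort <- simulate_cohort(cfg)
#> synthetic gland cohort: 2 patients, 30 samples (4 tumour regions + normal)

alleles <- simulate_allele_counts(cohort, n_sites = 500)
purity <- estimate_purity_all(alleles)
purity$truth <- round(cohort$truth$purity[purity$sample], 3)
head(purity[purity$truth > 0, ], 4)
#>    sample rho_hat ci_low ci_high n_sites truth
#>  P01_A_G1   0.718  0.703   0.734     500 0.710
#>  P01_A_G2   0.703  0.688   0.718     500 0.705
#>  P01_A_G3   0.681  0.666   0.696     500 0.676
#>  P01_B_G1   0.559  0.544   0.573     500 0.550
```

`rho_hat` is the maximum-likelihood tumour-cell fraction of each gland with
its 95% profile-likelihood interval; at 500 clonal sites and depth 30 the
estimates track the true simulated purities to well under 0.02.

```r
peaks <- simulate_peak_counts(cohort)
offsets <- cn_offset_matrix(cohort, peaks)   # size factors x CN adjustment
disp <- estimate_global_dispersion(peaks$counts, offsets,
          paste(cohort$samples$patient, cohort$samples$region == "E"))
#> 0.0542  (the generator's true dispersion is 0.05)

calls <- call_scaas(peaks$counts, cohort$samples, offsets, disp)
rec <- recurrence(calls, n_cases = 2, alpha = 0.01, min_frac = 0.2)
head(rec, 2)
#>    peak_id direction n_significant recurrent
#>  peak00053      loss             2      TRUE
#>  peak00001      gain             1      TRUE
```

Each row is a peak significantly altered in the same direction in enough
patients to count as recurrent; on this cohort every listed peak is a
planted alteration from the generator's ground truth.

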