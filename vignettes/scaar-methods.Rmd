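---
title: "Models and methods behind scaar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scaar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`scaar` analyses multi-region, single-gland multi-omic data from colorectal
tumours: chromatin accessibility (ATAC-seq), shallow whole-genome coverage,
somatic SNVs and expression, sampled as individual glands from four spatially
separated tumour regions (A–D) and one distant normal region (E) per
patient. A gland is close to a single clone, so per-gland measurements mix
exactly two cell populations — tumour cells at fraction ρ (the purity) and
contaminating normal cells — which is the modelling assumption every stage
below leans on. This vignette records the models, the tunable parameters and
the design decisions, including choices made where the design was genuinely
open.

## Purity from ATAC allele counts

At a clonal SNV carried on *m* of the *c* tumour copies of its locus, a read
sampled from a gland of purity ρ shows the alternative allele with
probability

$$p(\rho) = \frac{\rho m}{\rho c + 2 - 2\rho},$$

the denominator being the average copy number of the locus in the cell
mixture (normal cells contribute two reference copies). Alt counts are
binomial in the site depth, and ρ is estimated by minimizing the summed
binomial negative log-likelihood.

Numerical choices:

* **Exhaustive grid** over ρ ∈ [0, 1] (step 0.001) rather than a
  derivative-based optimizer: the likelihood can be flat near 0 when few
  informative sites exist, and the grid guarantees the global minimum at
  step resolution. Ties go to the smaller ρ (the conservative
  interpretation).
* **Site filters.** Only clonal sites are used; sites with depth < 5 are
  excluded by default (ATAC coverage per site is low, and very shallow
  sites carry almost no information — the threshold is configurable);
  sites with total copy number 0 are excluded and counted, since `p` is
  undefined there.
* The 95% interval is read off the likelihood curve at a half-width of 1.92
  (χ² with 1 df). The interval is our addition; the point estimate is the
  quantity used downstream. Samples enter SCAA analysis only at ρ > 0.4.

## Integer copy number from low-pass coverage

Binned (500-kb) log2 coverage ratios, median-centred per sample, are
segmented **jointly across the samples of a patient** by penalized least
squares: breakpoints minimize the within-segment squared error summed over
samples plus a per-breakpoint penalty. The solver is exact dynamic
programming per contig (up to a configurable bin cap, default 1,000) and
greedy binary splitting with the same cost beyond; the exact solver is
never costlier than the greedy one, which the test suite checks on random
tracks. The penalty default (0.2 per breakpoint at the test noise level) is
deliberately permissive: spurious breakpoints merely split a segment into
two with nearly equal means and do not harm the integer fit, while a missed
breakpoint does.

Given an integer tumour ploidy Ψ_t (in practice from deep WGS; supplied by
the generator here), the continuous copy number of a segment with mean
ratio *r* at purity ρ is

$$n(\rho) = \frac{2^{r}\,(2(1-\rho) + \rho\Psi_t) - 2(1-\rho)}{\rho},$$

and the goodness of fit at ρ is the segment-length-weighted squared
distance of *n* to the nearest non-negative integer. Purity candidates are
**local minima** of this curve on a 0.01 grid over [0.1, 1] (strictly lower
than both neighbours); the best local minimum wins, ties break toward
higher ρ (fewer degenerate subclonal interpretations); when no local
minimum exists — a flat, effectively diploid track — purity is defined as 1.
Negative integer states are clamped to zero.

Two practical refinements:

* **Modal recentring.** Median-centring leaves a residual offset whenever
  gains and losses are unbalanced (the median then sits off the
  ploidy-state cluster). Before scoring, the track is recentred on its
  length-weighted modal segment mean (kernel density mode, refined by a
  local weighted mean), bounded to ±0.15 so recentring can never relabel
  whole states (adjacent states are ≥ log2(3/2) ≈ 0.58 apart at ρ = 1).
* **Aliasing.** A genome whose only deviations from ploidy are +2 fits
  exactly as +1 states at a higher purity; this degeneracy is intrinsic to
  ploidy-grid fits and is resolved in real studies by deep-WGS ploidy and
  occasional manual override. The generator therefore guarantees at least
  one single-copy (±1) event per genome — which real colorectal genomes
  essentially always carry — making the fit identifiable.

## SCAA detection

Per-region peak calls (an input boundary — the caller itself is external)
are filtered at q-value < 0.1%, enrichment > 4.0 and at most the top 20,000
per region, then merged iteratively: the most significant remaining call
becomes the representative of everything overlapping it. A merged peak is
kept when supported by more than two tumour regions or by the normal panel.
Coordinates are 0-based half-open throughout. "Promoter" means a TSS
distance ≤ 1,000 bp for the recurrence analysis; the broader ±3,000 bp
annotation window used for general peak annotation is a separate named
constant.

Counts at a peak are modelled as negative binomial with a log link and a
fixed global dispersion. The offset of sample *s* at peak *i* is
`log(sf_s × cn_{is})` where `sf` is a TMM-style size factor (trimmed mean
of M-values against the sample whose upper quartile is closest to the mean
upper quartile, pseudo-count 0.5, 30%/5% trims, geometric-mean normalized)
and `cn` is the copy-number adjustment

$$\mathrm{cn} = \frac{2(1-\rho) + \pi\rho}{2(1-\rho) + \psi\rho}$$

(π the locus copy number, ψ the tumour ploidy; for pooled samples the
read-count-weighted average). Size factors are estimated on
**CN-adjusted** counts so that the known copy-number effect is not absorbed
twice — estimating them on raw counts leaves a systematic tumour-versus-
normal offset in aneuploid patients that visibly inflates the test's
type-I error.

The global dispersion is a single value shared by all peaks, estimated by
maximizing the Cox–Reid **adjusted** profile likelihood with per-group
means profiled out; the adjustment (half the log-determinant of the
mean-parameter information) removes the downward bias of plain plug-in
profiling, which we measured at ~20% of the dispersion on simulated data.
Each patient's glands (purity > 0.4, same-region glands as biological
replicates) are compared against the normal pool by a likelihood-ratio
test; per-patient significance at P ≤ 0.01 feeds recurrence, defined as
same-direction significance in at least ⌈20% of cases⌉.

Subclonality of a recurrent event within a tumour is the LRT between
`counts ~ purity + region` and `counts ~ purity` (NB, same offsets),
requiring at least two regions with two samples each; events are
BH-adjusted, require direction agreement with the bulk call, and gains
additionally require a called peak within 500 bp. Expression association
contrasts altered versus non-altered patients (normals their own level)
with an NB model and library-size offset — one-sided in the direction of
the accessibility change for promoters, two-sided for enhancers. The
expression matrix is pre-filtered to genes with ≥ 10 TPM in ≥ 5% of tumour
samples whose expression does not significantly *decrease* with purity
(per-gene linear model with patient as fixed covariate, BH FDR < 0.05) —
genes driven by contaminating normal cells would otherwise masquerade as
tumour signal.

## TF footprints

For each TF-site set (sites ≥ 1 kb apart within a TF, autosomes only,
stratified by TSS distance — proximal ≤ 2 kb, close 2–10 kb, distal > 10 kb
— crossed with in-peak/off-peak), insertions within ±1,000 bp of site
centres are tabulated by 5-bp insertion-size bin and signed distance,
orientation-flipped for minus-strand sites (our choice — the footprint is
then symmetric by construction). Rows are divided by the genome-wide
insertion count of the same size bin, and the mean over the 750–1,000 bp
flanks is subtracted per row, so any uniform background cancels exactly.

The scalar TF signal of a sample is the sum of (sample − pooled normal)
over sizes 25–120 bp and distances ±100 bp — the nucleosome-free central
block. The pooled normal is the read-weighted mean of the normal glands'
matrices (weighting unspecified in the field; read-weighting makes the
pool equal to the matrix of the concatenated reads). Signals are regressed
on `tsse * tsse_nf + purity:patient` with weights √reads; `tsse`/`tsse_nf`
are TSS-enrichment differences against the pool, and the per-patient purity
interaction coefficient — with its WLS t-test p-value, our choice of
significance measure — is the patient's TF summary. The 150 TFs most often
significant are clustered with Euclidean distance and complete linkage.

## Mutational signatures

Exposures of a fixed k × 96 signature matrix are fitted by non-negative
L1-regularized least squares via cyclic coordinate descent. The objective
is stated on the count scale, `||X − SᵀE||² + λ||E||₁`; internally the
problem is normalized to channel frequencies, which maps the penalty to
λ/N (N the catalogue size). This matters: a penalty of λ = 0.025 applied
naively on the frequency scale would dominate the residual and visibly
shrink (and distort the ratios of) exposures of a six-signature fit,
whereas on the count scale it is the mild regularization the default
intends. λ = 0 reduces exactly to non-negative least squares (checked
against an independent NNLS solver and a simplex grid search).

Region-stratified activities: catalogues are aggregated per region class,
multiplied channel-wise by (genome trinucleotide frequency) / (region
frequency) to undo the region's compositional bias, and fitted; jackknife
resampling (100 iterations, 90% of samples, ≥ 3 samples per cluster,
optionally excluding rare outlier clusters) gives means and 2.5/97.5
percentiles. We report both the **exposure** (relative, sums to 1) and the
**activity** — exposure × aggregated mutation count / region size — since
comparing a signature *between* regions needs the burden and the region's
genomic footprint, while composition *within* a region does not. Patient
clustering is k-means (fixed seed, 25 restarts) on the rows of the
1 − cosine similarity matrix of exposures; k defaults to 6, configurable
(published analyses describe both five- and six-cluster readings of the
same cohort).

## Cohort statistics

Fisher tests are the classic two-sided exact test (sum of hypergeometric
probabilities not exceeding the observed table's). MSI is called strictly
above 30% mutated microsatellites — the boundary itself is MSS, a choice we
fixed since the source threshold is stated as a critical value without
boundary behaviour; a clinical override flag reproduces reclassification of
low-purity cases. The burden comparison subsamples carcinoma reads to the
median adenoma total by sequential hypergeometric draws (binomial thinning
preserves the NB family, so subsampled carcinomas remain distributionally
comparable to adenomas), counts per-lesion gains/losses against a
trimmed-mean-scaled normal reference — the robust scaling prevents a few
true gains from depressing the baseline and manufacturing fake losses —
and applies Welch's two-sided t-test per direction (the unequal-variance
variant; the source states only "t-test"). Heritability: pairwise SCAA
distance is regressed on a same-region indicator plus covariate
differences, with significance by permutation of region labels (pairwise
distances are not independent, so the parametric ANOVA p would be
anti-conservative); the genetic–epigenetic association is a partial Mantel
correlation controlling for purity differences (999 permutations).

## The synthetic cohort generator

The generator is first-class, tested code and defines the study conditions:
per default 4 tumour regions plus normals, ≥ 2 glands per region
(biological replicates for the subclonality test), tumour purity uniform on
[0.3, 0.95] (the within-tumour purity distribution is unreported in real
cohorts; uniform is a modelling convenience, and an explicit purity vector
can be supplied), depth 30 per SNV site, NB dispersion 0.05, planted gains
×3 and losses ×⅓, 25% of planted SCAAs confined to half of the regions.
The synthetic genome is five 10-Mb contigs with a fabricated TSS map,
enhancer map and trinucleotide content table. Copy-number truth is
segment-constant with shared breakpoints per patient, arm-scale segments
(≥ 2 Mb), the nominal ploidy as modal state (≥ 60% of bins) and at least
one ±1 event (see the aliasing note above). Fragment insertion sizes mix a
shifted-exponential nucleosome-free component (mode ≈ 60 bp) with Gaussian
nucleosomal components at 200/400 bp; planted footprint effects scale the
expected central nucleosome-free density at target sites by
1 + (effect − 1)ρ, i.e. linearly in purity. One global seed fans out to
per-stage child seeds through a counter scheme, so stages re-run
independently and reproducibly.

What the generator does **not** emulate: read sequences, mappability and GC
bias, fragment-level spatial autocorrelation, peak-width variation linked
to signal, subclonal copy-number evolution, and cell-type mixtures beyond
the two-population purity model. Passing the recovery suites therefore
shows the estimators are correct and calibrated **under the stated model**,
not that real-data biases are absent; on real data the external
normalization steps (mappability/GC correction, peak calling) sit upstream
of this package's input boundary.

## Validation scale and known limitations

The test and acceptance suites run at desk scale: 20 glands × 500 SNVs for
purity recovery; 50 patients × 3 low-pass samples for copy number; 2,000
null peaks and 200 power replicates for the SCAA test; ~100 events per arm
for subclonality; 4 TFs × 400 sites × 5 purity levels for footprints; 10⁵
mutations for exposures; 50 replicates for the burden pattern. These sizes
were chosen as the smallest at which the binomial/NB sampling error is
comfortably below the tolerance being asserted.

Known limitations: the purity/ploidy grid fit remains unidentifiable for
genomes with no odd-offset copy-number event (handled by generator design
here, by deep-WGS ploidy and manual review in practice); the recurrence
ranking with and without CN adjustment agrees only strongly, not
perfectly, when single-copy gains occur in near-pure glands — such events
carry genuine accessibility-scale signal, which is precisely why the
adjustment exists; exact numerical agreement with any published
count-model implementation is a non-goal (calibration is the contract);
and the NB offset trick is exactly scale-invariant only in the Poisson
limit.
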